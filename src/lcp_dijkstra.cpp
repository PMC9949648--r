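#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EARTH_R_KM = 6371.0088;

// great-circle distance between two cell centers (degrees in, km out)
static inline double gcKm(double lon1, double lat1, double lon2, double lat2) {
  const double toRad = M_PI / 180.0;
  double dLat = (lat2 - lat1) * toRad, dLon = (lon2 - lon1) * toRad;
  double a = std::sin(dLat / 2) * std::sin(dLat / 2) +
             std::cos(lat1 * toRad) * std::cos(lat2 * toRad) *
                 std::sin(dLon / 2) * std::sin(dLon / 2);
  double s = std::sqrt(a);
  if (s > 1.0) s = 1.0;
  return 2.0 * EARTH_R_KM * std::asin(s);
}

// Dijkstra over the 8-connected lattice. Edge weight between neighbors i, j:
// d(i, j) * (cost_i + cost_j) / 2. Node order is row-major ((row, col)
// lexicographic); on cost ties the smaller predecessor index wins, which
// makes the recovered path deterministic.
// [[Rcpp::export]]
List lcp_dijkstra(NumericMatrix cost, int startR, int startC, int endR,
                  int endC, double xOrigin, double yOrigin, double cellSize,
                  bool unitDistance) {
  const int nr = cost.nrow(), nc = cost.ncol(), n = nr * nc;
  std::vector<double> lonC(nc), latC(nr);
  for (int c = 0; c < nc; ++c) lonC[c] = xOrigin + (c + 0.5) * cellSize;
  for (int r = 0; r < nr; ++r) latC[r] = yOrigin - (r + 0.5) * cellSize;

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, -1);
  std::vector<bool> done(n, false);
  typedef std::pair<double, int> QN; // (distance, row-major node index)
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  const int sIdx = startR * nc + startC, eIdx = endR * nc + endC;
  dist[sIdx] = 0.0;
  pq.push(QN(0.0, sIdx));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    if (u == eIdx) break;
    int ur = u / nc, uc = u % nc;
    double cu = cost(ur, uc);
    if (!R_finite(cu)) continue;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      double cv = cost(vr, vc);
      if (!R_finite(cv)) continue;
      double d;
      if (unitDistance)
        d = (dr[k] != 0 && dc[k] != 0) ? M_SQRT2 : 1.0;
      else
        d = gcKm(lonC[uc], latC[ur], lonC[vc], latC[vr]);
      double nd = top.first + d * 0.5 * (cu + cv);
      int v = vr * nc + vc;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(QN(nd, v));
      } else if (nd == dist[v] && u < pred[v]) {
        pred[v] = u; // deterministic tie-break: smallest predecessor
      }
    }
  }

  if (!R_finite(dist[eIdx]))
    return List::create(_["totalCost"] = R_PosInf,
                        _["rows"] = IntegerVector(0),
                        _["cols"] = IntegerVector(0));

  std::vector<int> chain;
  for (int v = eIdx; v != -1; v = pred[v]) chain.push_back(v);
  const int m = (int)chain.size();
  IntegerVector rows(m), cols(m);
  for (int i = 0; i < m; ++i) {
    int v = chain[m - 1 - i];
    rows[i] = v / nc;
    cols[i] = v % nc;
  }
  return List::create(_["totalCost"] = dist[eIdx], _["rows"] = rows,
                      _["cols"] = cols);
}
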