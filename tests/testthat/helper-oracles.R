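# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and never share code paths with the package implementation.

# Exhaustive Bellman-Ford relaxation over the 8-connected lattice with the
# trapezoidal edge weight d * (c_i + c_j) / 2. Iterates full sweeps until no
# distance improves. Returns the minimum total cost start -> end.
bellmanFordCost <- function(cost, start, end, grid = NULL, unitDistance = TRUE) {
  nr <- nrow(cost); nc <- ncol(cost); n <- nr * nc
  idx <- function(r, c) (r - 1L) * nc + c # row-major like the implementation
  edges <- list()
  centers <- if (!unitDistance) {
    ctr <- cellCenters(grid)
    list(lon = ctr$lon, lat = ctr$lat)
  }
  tails <- integer(0); heads <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.finite(cost[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.finite(cost[r2, c2])) next
      d <- if (unitDistance) sqrt(dr^2 + dc^2) else
        haversineKm(centers$lon[c], centers$lat[r],
                    centers$lon[c2], centers$lat[r2])
      tails <- c(tails, idx(r, c)); heads <- c(heads, idx(r2, c2))
      w <- c(w, d * (cost[r, c] + cost[r2, c2]) / 2)
    }
  }
  dist <- rep(Inf, n)
  dist[idx(start[1], start[2])] <- 0
  repeat {
    cand <- dist[tails] + w
    nd <- dist
    ord <- order(heads, cand)
    hh <- heads[ord]; cc <- cand[ord]
    first <- !duplicated(hh)
    best <- cc[first]; node <- hh[first]
    improved <- best < nd[node]
    if (!any(improved)) break
    nd[node[improved]] <- best[improved]
    dist <- nd
  }
  dist[idx(end[1], end[2])]
}

# Queue-based 4-connected flood fill, scalar and obvious.
bfsFlood <- function(z, level, seedR, seedC) {
  nr <- nrow(z); nc <- ncol(z)
  wet <- !is.na(z) & z <= level
  out <- matrix(FALSE, nr, nc)
  if (!wet[seedR, seedC]) return(out)
  queue <- list(c(seedR, seedC))
  out[seedR, seedC] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && wet[r, c] && !out[r, c]) {
        out[r, c] <- TRUE
        queue <- c(queue, list(c(r, c)))
      }
    }
  }
  out
}

# Spherical destination point: start (lon, lat), initial bearing (deg),
# distance (km). Used to place points at exact great-circle offsets.
destinationPoint <- function(lon, lat, bearingDeg, distKm) {
  R <- 6371.0088
  toRad <- pi / 180
  d <- distKm / R
  th <- bearingDeg * toRad
  phi1 <- lat * toRad; lam1 <- lon * toRad
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(d) * cos(phi1),
                       cos(d) - sin(phi1) * sin(phi2))
  c(lon = lam2 / toRad, lat = phi2 / toRad)
}

# Hand bilinear interpolation at a fractional (row, col) position (0-based)
# of a matrix, no snapping cleverness.
bilinearAt <- function(m, fr, fc) {
  r0 <- floor(fr); c0 <- floor(fc)
  tr <- fr - r0; tc <- fc - c0
  (1 - tr) * (1 - tc) * m[r0 + 1, c0 + 1] +
    (1 - tr) * tc * m[r0 + 1, c0 + 2] +
    tr * (1 - tc) * m[r0 + 2, c0 + 1] +
    tr * tc * m[r0 + 2, c0 + 2]
}
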