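# Independent oracles and small fixture builders shared across tests.

# Full-rank thin-plate smoother: penalized least squares in the radial
# basis with the exact polynomial side condition, solved by brute force.
# Returns fitted values at the data points.
full_tps_fit <- function(xy, y, lambda) {
  n <- nrow(xy)
  r <- as.matrix(dist(xy))
  E <- matrix(0, n, n)
  E[r > 0] <- r[r > 0]^2 * log(r[r > 0])
  Tm <- cbind(1, xy)
  qrT <- qr(Tm)
  Z <- qr.Q(qrT, complete = TRUE)[, -(1:3), drop = FALSE]
  A <- cbind(E %*% Z, Tm)
  Pen <- matrix(0, ncol(A), ncol(A))
  Pen[1:(n - 3), 1:(n - 3)] <- lambda * t(Z) %*% E %*% Z
  drop(A %*% solve(crossprod(A) + Pen, crossprod(A, y)))
}

# WAIC by the naive (unstabilized) textbook formula.
naive_waic <- function(loglik) {
  lppd <- sum(log(colMeans(exp(loglik))))
  p_waic <- sum(apply(loglik, 2, var))
  -2 * (lppd - p_waic)
}

# Moore-Penrose pseudo-inverse via eigendecomposition (symmetric input).
sym_pinv <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

# Small deterministic geography on a jittered grid (no Delaunay needed):
# rook adjacency on the grid cells.
tiny_geography <- function(nx = 4, ny = 4, pop = 2e4) {
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  n <- nrow(grid)
  set.seed(99)
  cents <- cbind((grid$ix - 0.5) / nx + runif(n, -0.1, 0.1) / nx,
                 (grid$iy - 0.5) / ny + runif(n, -0.1, 0.1) / ny)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(grid$ix[i] - grid$ix[j]) + abs(grid$iy[i] - grid$iy[j]) == 1)
      W[i, j] <- 1
  }
  geography(sprintf("g%02d", seq_len(n)), cents, rep(pop, n), W)
}

# GeoJSON FeatureCollection of axis-aligned unit squares, written to a
# temporary file; squares given as a list of (x0, y0) lower-left corners.
write_squares_geojson <- function(corners, ids = NULL) {
  ids <- ids %||% sprintf("sq%d", seq_along(corners))
  feats <- lapply(seq_along(corners), function(i) {
    x0 <- corners[[i]][1]; y0 <- corners[[i]][2]
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    list(type = "Feature",
         properties = list(area_id = ids[[i]]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
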