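#' Connectivity coordinates
#'
#' A 2-D coordinate system describing the relative connectivity of areas:
#' either scaled geographic centroids (distance-based connectivity) or a
#' multidimensional-scaling embedding of a symmetric connectivity measure
#' (e.g. modelled human movement). Each axis is affinely scaled to [0, 1] so
#' surfaces built on different systems live on a common support.
#'
#' @param coords numeric n x 2 matrix.
#' @param source_label free-text label, e.g. `"distance"` or `"movement"`.
#' @param scaled logical; have the axes been min-max scaled already?
#' @return An object of class `sm_coords`.
#' @export
connectivity_coordinates <- function(coords, source_label = "distance",
                                     scaled = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns")
  structure(list(coords = unname(coords), source_label = source_label,
                 scaled = scaled),
            class = "sm_coords")
}

#' @export
print.sm_coords <- function(x, ...) {
  cat(sprintf("<sm_coords> %d areas, source '%s'%s\n", nrow(x$coords),
              x$source_label, if (x$scaled) ", scaled to [0,1]" else ""))
  invisible(x)
}

#' Min-max scale planar coordinates to the unit square
#'
#' Applies the per-axis affine map \eqn{x \to (x - \min x)/(\max x - \min x)}
#' so each axis has minimum 0 and maximum 1, preserving area order.
#' Idempotent: scaling already-scaled coordinates changes nothing.
#'
#' @param raw n x 2 numeric matrix, or an `sm_coords` object.
#' @param source_label label carried to the result (defaults to the input's
#'   label, or `"distance"` for a bare matrix).
#' @return `sm_coords` with coordinates in the unit square.
#' @export
scale_coordinates <- function(raw, source_label = NULL) {
  if (inherits(raw, "sm_coords")) {
    source_label <- source_label %||% raw$source_label
    raw <- raw$coords
  }
  source_label <- source_label %||% "distance"
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least two areas to scale coordinates")
  out <- raw
  for (j in seq_len(ncol(raw))) {
    rng <- range(raw[, j])
    if (diff(rng) <= 0)
      stop(sprintf("coordinate axis %d is constant; cannot scale to [0,1]", j))
    out[, j] <- (raw[, j] - rng[1L]) / diff(rng)
  }
  connectivity_coordinates(out, source_label, scaled = TRUE)
}

#' Symmetric flow matrix
#'
#' Validates (and if needed symmetrizes) a non-negative flow matrix. The
#' modelling framework assumes the number of people travelling to an area
#' equals the number returning; asymmetric input is averaged with its
#' transpose and a warning is raised.
#'
#' @param flows n x n non-negative matrix.
#' @return matrix of class `sm_flows`, symmetric with zero diagonal.
#' @export
flow_matrix <- function(flows) {
  flows <- as.matrix(flows)
  if (nrow(flows) != ncol(flows)) stop("flow matrix must be square")
  if (any(!is.finite(flows)) || any(flows < 0))
    stop("flows must be finite and non-negative")
  if (!isTRUE(all.equal(unname(flows), unname(t(flows)), tolerance = 1e-8))) {
    warning("asymmetric flow matrix symmetrized as (M + t(M))/2")
    flows <- (flows + t(flows)) / 2
  }
  diag(flows) <- 0
  class(flows) <- c("sm_flows", class(flows))
  flows
}

#' Gravity-model movement flows
#'
#' Classic gravity model: the flow between areas i and j is proportional to
#' the product of their populations and decays with distance,
#' \eqn{f_{ij} = \kappa N_i N_j / d_{ij}^\gamma}, with Euclidean centroid
#' distance \eqn{d_{ij}}. Symmetric by construction; diagonal zero.
#'
#' @param populations n strictly positive populations.
#' @param centroids n x 2 planar centroid coordinates (distinct rows).
#' @param gamma distance-decay exponent (> 0); default 2.
#' @param kappa proportionality constant (> 0); default 1.
#' @return `sm_flows` matrix.
#' @export
gravity_flows <- function(populations, centroids, gamma = 2, kappa = 1) {
  stopifnot_scalar_number(gamma, "gamma", positive = TRUE)
  stopifnot_scalar_number(kappa, "kappa", positive = TRUE)
  centroids <- as.matrix(centroids)
  n <- length(populations)
  if (nrow(centroids) != n) stop("populations and centroids disagree on n")
  if (any(populations <= 0)) stop("populations must be positive")
  d <- as.matrix(stats::dist(centroids))
  off <- upper.tri(d) | lower.tri(d)
  if (any(d[off] == 0))
    stop("coincident centroids give zero distance; gravity flow undefined")
  f <- kappa * outer(populations, populations) / d^gamma
  diag(f) <- 0
  flow_matrix(unname(f))
}

#' Convert symmetric flows to a dissimilarity matrix
#'
#' MDS needs a dissimilarity, i.e. small values for strongly connected
#' pairs; a monotone decreasing transform of the flows supplies one.
#'
#' * `reciprocal` (default): \eqn{1/(1+f)} — bounded in (0, 1], handles
#'   zero flows.
#' * `max_minus`: \eqn{\max(f) - f} on the off-diagonal.
#' * `neg_log`: \eqn{-\log(f/\max(f))}; requires all off-diagonal flows > 0.
#'
#' @param flows symmetric non-negative matrix (`sm_flows` or plain).
#' @param transform one of `"reciprocal"`, `"max_minus"`, `"neg_log"`.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
flows_to_dissimilarity <- function(flows,
                                   transform = c("reciprocal", "max_minus",
                                                 "neg_log")) {
  transform <- match.arg(transform)
  if (!inherits(flows, "sm_flows")) flows <- flow_matrix(flows)
  f <- unclass(flows)
  off <- row(f) != col(f)
  fmax <- max(f[off])
  d <- f
  d[] <- 0
  if (transform == "reciprocal") {
    d[off] <- 1 / (1 + f[off])
  } else if (transform == "max_minus") {
    d[off] <- fmax - f[off]
  } else {
    if (any(f[off] == 0))
      stop("neg_log transform requires strictly positive off-diagonal flows")
    d[off] <- -log(f[off] / fmax)
  }
  diag(d) <- 0
  unname(d)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric dissimilarity matrix into `dim` Cartesian coordinates:
#' double-centre \eqn{-\tfrac12 D^2}, take the leading eigenpairs with
#' positive eigenvalues and scale the eigenvectors by the square roots of
#' their eigenvalues. Deterministic: each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive. Dimensions whose eigenvalues are not
#' positive are clamped to zero columns (with a warning). The configuration
#' is finally min-max scaled to the unit square via [scale_coordinates()].
#'
#' @param dissimilarity symmetric n x n matrix, zero diagonal, non-negative.
#' @param dim embedding dimension (default 2, < n).
#' @param source_label label for the resulting coordinate system.
#' @param scale if `FALSE`, return the raw (unscaled) configuration — useful
#'   for checking exact distance recovery.
#' @return `sm_coords` (or a bare matrix when `scale = FALSE`).
#' @export
classical_mds <- function(dissimilarity, dim = 2L, source_label = "movement",
                          scale = TRUE) {
  D <- as.matrix(dissimilarity)
  n <- nrow(D)
  if (ncol(D) != n) stop("dissimilarity must be square")
  if (!isTRUE(all.equal(D, t(D)))) stop("dissimilarity must be symmetric")
  if (any(D < 0)) stop("dissimilarity must be non-negative")
  if (any(diag(D) != 0)) stop("dissimilarity must have a zero diagonal")
  if (dim >= n) stop("embedding dimension must be smaller than n")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  npos <- sum(e$values[seq_len(dim)] > 1e-12 * max(abs(e$values)))
  X <- matrix(0, n, dim)
  if (npos < dim)
    warning(sprintf("only %d positive eigenvalue(s); padding %d dimension(s) with zeros",
                    npos, dim - npos))
  for (k in seq_len(npos)) {
    v <- e$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v  # reproducible sign convention
    X[, k] <- v * sqrt(e$values[k])
  }
  if (!scale) return(X)
  scale_coordinates(X, source_label = source_label)
}

#' Movement connectivity coordinates from a flow matrix
#'
#' Convenience pipeline: flows are converted to a dissimilarity and
#' embedded in 2-D by [classical_mds()]. With `transform = "auto"` the
#' `neg_log` transform is used when every off-diagonal flow is strictly
#' positive (the natural additive dissimilarity for gravity-type flows,
#' whose raw magnitudes span many orders) and the bounded `reciprocal`
#' transform otherwise.
#'
#' @param flows symmetric non-negative flow matrix.
#' @param transform `"auto"` (default) or one of the
#'   [flows_to_dissimilarity()] transforms.
#' @param source_label label for the coordinate system.
#' @return `sm_coords` scaled to the unit square.
#' @export
movement_coordinates <- function(flows, transform = "auto",
                                 source_label = "movement") {
  if (!inherits(flows, "sm_flows")) flows <- flow_matrix(flows)
  if (transform == "auto") {
    f <- unclass(flows)
    transform <- if (all(f[row(f) != col(f)] > 0)) "neg_log" else "reciprocal"
  }
  classical_mds(flows_to_dissimilarity(flows, transform), 2L,
                source_label = source_label)
}
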