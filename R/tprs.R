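#' Thin-plate regression spline basis over 2-D connectivity coordinates
#'
#' Builds a rank-`K` thin-plate regression spline smoother for a surface
#' \eqn{f(x, z) = \sum_j \beta_j b_j(x, z)} following the eigen-truncation
#' construction: the full thin-plate radial basis \eqn{\eta(r) = r^2 \log r}
#' is evaluated at every pair of data points, the resulting n x n matrix is
#' eigendecomposed and the leading eigenvectors (by absolute eigenvalue) are
#' retained; the orthogonality-to-polynomials side condition is absorbed so
#' the truncated wiggly block carries the curvature penalty, and the
#' polynomial null space (1, x, z) is appended unpenalized.
#'
#' For identifiability alongside a model intercept (and alongside other
#' surfaces) the sum-to-zero constraint \eqn{\sum_i f(x_i) = 0} is absorbed:
#' the intercept column is dropped and the remaining columns are centred.
#' The returned object holds the n x (K-1) design matrix `X`, the wiggliness
#' penalty `P1` (zero on the polynomial block) and the null-space penalty
#' `P0` (identity on the two remaining polynomial columns, zero elsewhere),
#' so that the Bayesian coefficient prior is
#' \eqn{\beta \sim N(0, (\lambda_0 P_0 + \lambda_1 P_1)^{-1})}.
#'
#' @param coords `sm_coords` (or n x 2 matrix) of connectivity coordinates;
#'   duplicate rows are rejected.
#' @param K total basis dimension before constraint absorption (>= 4, < n);
#'   default 30, a pragmatic size for desk-scale MCMC.
#' @param label name used for this surface in model output.
#' @return object of class `sm_basis` with elements `X`, `P1`, `P0`, `K`,
#'   `ncoef` (= K - 1), `null_cols`, `coords_ref`, `label`, `constraint`.
#' @export
build_tprs_basis <- function(coords, K = 30L, label = NULL) {
  if (inherits(coords, "sm_coords")) {
    label <- label %||% coords$source_label
    xy <- coords$coords
  } else {
    xy <- as.matrix(coords)
    label <- label %||% "smooth"
  }
  n <- nrow(xy)
  K <- as.integer(K)
  if (K <= 3L) stop("K must be at least 4 (3 dimensions go to the polynomial null space)")
  if (n < K) stop("need at least K data points (K = n gives the full-rank smoother)")
  if (anyDuplicated(xy) > 0L) stop("duplicate coordinate rows are not allowed")

  # radial basis eta(r) = r^2 log r (positive multiple of the thin-plate
  # Green's function for d = 2, m = 2); eta(0) = 0
  r <- as.matrix(stats::dist(xy))
  E <- matrix(0, n, n)
  pos <- r > 0
  E[pos] <- r[pos]^2 * log(r[pos])

  Tm <- cbind(1, xy)                       # polynomial null space: 1, x, z

  eg <- eigen(E, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(K)]
  ord <- ord[order(ord)]                   # deterministic tie-break: eigen() order
  U <- eg$vectors[, ord, drop = FALSE]
  ev <- eg$values[ord]
  for (k in seq_len(K)) {                  # reproducible eigenvector signs
    if (U[which.max(abs(U[, k])), k] < 0) U[, k] <- -U[, k]
  }

  # absorb the side condition T' delta = 0 (delta = U delta~): Z spans the
  # null space of (T' U), a K x (K - 3) matrix
  C <- t(Tm) %*% U                         # 3 x K
  qrC <- qr(t(C))
  Z <- qr.Q(qrC, complete = TRUE)[, -(seq_len(qrC$rank)), drop = FALSE]
  if (ncol(Z) != K - 3L) stop("degenerate configuration: constraint rank deficiency")

  Xw <- U %*% (ev * Z)                     # E U Z = U diag(ev) Z
  P1w <- crossprod(Z, ev * Z)
  P1w <- (P1w + t(P1w)) / 2
  # clip tiny negative eigenvalues arising from finite arithmetic: the
  # curvature form is PSD on the constrained space
  ep <- eigen(P1w, symmetric = TRUE)
  vals <- pmax(ep$values, 0)
  P1w <- ep$vectors %*% (vals * t(ep$vectors))
  P1w <- (P1w + t(P1w)) / 2

  # full (unconstrained) design: [wiggly | 1 | x | z]; drop the intercept
  # column and centre the rest -> sum-to-zero constraint absorbed
  Xf <- cbind(Xw, xy)
  cm <- colMeans(Xf)
  X <- sweep(Xf, 2L, cm)

  p <- K - 1L
  P1 <- matrix(0, p, p)
  P1[seq_len(K - 3L), seq_len(K - 3L)] <- P1w
  P0 <- matrix(0, p, p)
  null_cols <- (K - 2L):p
  diag(P0)[null_cols] <- 1

  structure(
    list(X = X, P1 = P1, P0 = P0, K = K, ncoef = p, null_cols = null_cols,
         rank_P1 = K - 3L, rank_P0 = 2L,
         coords_ref = xy, label = label,
         constraint = "sum-to-zero (intercept dropped, columns centred)"),
    class = "sm_basis")
}

#' @export
print.sm_basis <- function(x, ...) {
  cat(sprintf("<sm_basis> '%s': n = %d, K = %d (%d coefficients after constraint)\n",
              x$label, nrow(x$X), x$K, x$ncoef))
  invisible(x)
}

#' Prior precision of the spline coefficients
#'
#' The wiggliness penalty alone is rank deficient (polynomials are
#' unpenalized), so the Gaussian prior precision for \eqn{\beta} is the
#' full-rank combination \eqn{P_0 \lambda_0 + P_1 \lambda_1}: the null-space
#' penalty makes the prior proper.
#'
#' @param basis `sm_basis`.
#' @param lambda0 null-space smoothing parameter (> 0).
#' @param lambda1 wiggliness smoothing parameter (> 0).
#' @return symmetric positive-definite `ncoef` x `ncoef` matrix.
#' @export
prior_precision <- function(basis, lambda0, lambda1) {
  stopifnot(inherits(basis, "sm_basis"))
  stopifnot_scalar_number(lambda0, "lambda0", positive = TRUE)
  stopifnot_scalar_number(lambda1, "lambda1", positive = TRUE)
  basis$P0 * lambda0 + basis$P1 * lambda1
}

#' Evaluate a smooth surface at the data points
#'
#' Returns \eqn{X \beta}; by the absorbed sum-to-zero constraint the values
#' average to (numerically) zero over areas.
#'
#' @param basis `sm_basis`.
#' @param beta coefficient vector of length `basis$ncoef`.
#' @return numeric vector of n surface values.
#' @export
evaluate_smooth <- function(basis, beta) {
  stopifnot(inherits(basis, "sm_basis"))
  beta <- as.numeric(beta)
  if (length(beta) != basis$ncoef)
    stop(sprintf("beta has length %d but the basis has %d coefficients",
                 length(beta), basis$ncoef))
  drop(basis$X %*% beta)
}
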