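#' Specify a Bayesian disease-mapping model
#'
#' Assembles the hierarchical count model
#' \deqn{\log E(y_i) = \log \xi_i + \alpha + S_i,}
#' where \eqn{S_i} is the sum of the requested random terms: one or more
#' penalized spline surfaces over connectivity coordinates, an iid
#' heterogeneity term \eqn{v_i \sim N(0, \sigma_v^2)}, or (comparator mode)
#' a BYM2 term combining a scaled intrinsic-CAR field and an iid field
#' through a mixing parameter \eqn{\phi} and precision scale \eqn{\tau}.
#' Likelihood families: Poisson, negative binomial (mean \eqn{\mu}, variance
#' \eqn{\mu + \mu^2/\psi}) or binomial with a logit link (needs `trials`
#' instead of an offset).
#'
#' @param family `"poisson"`, `"negbin"` or `"binomial"`.
#' @param offset numeric n-vector \eqn{\log \xi_i}, typically
#'   `log(population / 1e5)` so rates are per 100 000. Ignored (and must be
#'   `NULL`) for the binomial family.
#' @param smooth_terms list of [build_tprs_basis()] objects (possibly
#'   named); labels default to each basis's own label.
#' @param include_iid include the unstructured heterogeneity term `v`?
#' @param comparator `"none"` (spline model) or `"bym2"` (CAR comparator;
#'   `smooth_terms` must then be empty and `adjacency` supplied).
#' @param adjacency binary symmetric matrix for the BYM2 comparator.
#' @param trials integer n-vector of binomial trials.
#' @param priors named list overriding any of the default hyperpriors:
#'   `alpha_sd` (10), `lambda_shape` (0.05), `lambda_rate` (0.005),
#'   `tau_v_shape` (0.05), `tau_v_rate` (0.005), `tau_shape` (1),
#'   `tau_rate` (0.01), `psi_shape` (0.01), `psi_rate` (0.01). The BYM2
#'   mixing parameter has a Uniform(0, 1) prior.
#' @return object of class `sm_model_spec`.
#' @export
model_spec <- function(family = c("poisson", "negbin", "binomial"),
                       offset = NULL, smooth_terms = list(),
                       include_iid = TRUE,
                       comparator = c("none", "bym2"),
                       adjacency = NULL, trials = NULL, priors = list()) {
  family <- match.arg(family)
  comparator <- match.arg(comparator)
  defaults <- list(alpha_sd = 10, lambda_shape = 0.05, lambda_rate = 0.005,
                   tau_v_shape = 0.05, tau_v_rate = 0.005,
                   tau_shape = 1, tau_rate = 0.01,
                   psi_shape = 0.01, psi_rate = 0.01)
  unknown <- setdiff(names(priors), names(defaults))
  if (length(unknown)) stop("unknown prior settings: ", paste(unknown, collapse = ", "))
  priors <- utils::modifyList(defaults, priors)

  if (family == "binomial") {
    if (!is.null(offset)) stop("binomial family takes 'trials', not an offset")
    if (is.null(trials)) stop("binomial family requires a trials vector")
    n <- length(trials)
  } else {
    if (is.null(offset)) stop("count families require an offset (log xi)")
    n <- length(offset)
  }

  if (comparator == "bym2") {
    if (length(smooth_terms)) stop("BYM2 comparator takes no smooth terms")
    if (is.null(adjacency)) stop("BYM2 comparator requires an adjacency matrix")
    check_adjacency(as.matrix(adjacency), n)
  } else {
    if (!length(smooth_terms) && !include_iid)
      message("intercept-only model: no random terms requested")
    for (b in smooth_terms) {
      if (!inherits(b, "sm_basis")) stop("smooth_terms must be sm_basis objects")
      if (nrow(b$X) != n) stop("a smooth term's n does not match the data")
    }
    labels <- names(smooth_terms) %||% vapply(smooth_terms, `[[`, "", "label")
    if (is.null(names(smooth_terms)))
      names(smooth_terms) <- vapply(smooth_terms, `[[`, "", "label")
    if (anyDuplicated(names(smooth_terms)))
      stop("smooth term labels must be unique")
  }

  structure(
    list(family = family, offset = offset, smooth_terms = smooth_terms,
         include_iid = include_iid, comparator = comparator,
         adjacency = if (is.null(adjacency)) NULL else unname(as.matrix(adjacency)),
         trials = trials, priors = priors, n = n),
    class = "sm_model_spec")
}

#' @export
print.sm_model_spec <- function(x, ...) {
  terms <- c(names(x$smooth_terms),
             if (x$include_iid && x$comparator == "none") "iid",
             if (x$comparator == "bym2") "bym2")
  cat(sprintf("<sm_model_spec> %s, n = %d, terms: %s\n", x$family, x$n,
              if (length(terms)) paste(terms, collapse = " + ") else "(intercept only)"))
  invisible(x)
}

#' Intrinsic CAR precision structure
#'
#' For binary neighbourhood weights the conditional specification — each
#' area's effect is normal around the average of its neighbours with
#' variance inversely proportional to the neighbour count — corresponds to
#' the joint (improper) Gaussian with precision \eqn{Q = D - W}, where `D`
#' is the diagonal of row sums. `Q` annihilates constants per connected
#' component (rank n minus the number of components); islands yield zero
#' rows and are handled downstream.
#'
#' @param W binary symmetric adjacency matrix, zero diagonal.
#' @return n x n precision structure matrix (up to the scale \eqn{1/\sigma_s^2}).
#' @export
icar_precision <- function(W) {
  W <- as.matrix(W)
  check_adjacency(W)
  diag(rowSums(W)) - W
}

#' BYM2 scaling factor of an adjacency graph
#'
#' The structured BYM2 component must have unit generalized variance so the
#' mixing parameter is interpretable; the required factor is the geometric
#' mean of the marginal variances of the intrinsic CAR field, i.e. of the
#' diagonal of the generalized inverse of \eqn{Q = D - W}, computed per
#' connected component (sum-to-zero within each component). Multiplying `Q`
#' by this factor makes that geometric mean 1. Islands are excluded (they
#' receive independent standard-normal effects in the model).
#'
#' @param W binary symmetric adjacency matrix.
#' @return positive scalar scaling factor.
#' @export
bym2_scaling_factor <- function(W) {
  W <- as.matrix(W)
  check_adjacency(W)
  Q <- icar_precision(W)
  comp <- connected_components(W)
  sizes <- table(comp)
  use <- as.integer(names(sizes)[sizes > 1])
  if (!length(use))
    stop("all areas are islands: no connected component of size > 1")
  vars <- numeric(0)
  for (cc in use) {
    idx <- which(comp == cc)
    Qc <- Q[idx, idx, drop = FALSE]
    e <- eigen(Qc, symmetric = TRUE)
    keep <- e$values > 1e-10 * max(e$values)
    Vg <- e$vectors[, keep, drop = FALSE]
    dg <- rowSums(sweep(Vg, 2L, e$values[keep], "/") * Vg)  # diag of ginv(Qc)
    vars <- c(vars, dg)
  }
  geometric_mean(vars)
}

#' Combine BYM2 components into the spatial random term
#'
#' \deqn{S = \tau^{-1/2}\,(\sqrt{\phi}\, u^* + \sqrt{1-\phi}\, v^*),}
#' where \eqn{u^*} is the scaled intrinsic-CAR field (unit generalized
#' variance), \eqn{v^*} iid standard normal, \eqn{\phi \in [0,1]} the share
#' of spatially structured variation and \eqn{\tau} the overall precision.
#' \eqn{\phi = 1} recovers an intrinsic CAR model; \eqn{\phi = 0} pure
#' heterogeneity.
#'
#' @param phi mixing parameter in \[0, 1\].
#' @param tau precision scale (> 0).
#' @param u_star n structured (scaled ICAR) effects.
#' @param v_star n unstructured standard-normal effects.
#' @return numeric vector S of length n.
#' @export
bym2_combine <- function(phi, tau, u_star, v_star) {
  stopifnot_scalar_number(phi, "phi")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  if (length(u_star) != length(v_star)) stop("u_star and v_star lengths differ")
  (sqrt(phi) * u_star + sqrt(1 - phi) * v_star) / sqrt(tau)
}

#' Linear predictor of the hierarchical model
#'
#' Sums the offset, intercept and all supplied random-term value vectors:
#' \eqn{\eta_i = \log \xi_i + \alpha + \sum_k t_{k,i}} for the count
#' families, or the logit-scale \eqn{\alpha + \sum_k t_{k,i}} (no offset)
#' for the binomial family.
#'
#' @param spec `sm_model_spec`.
#' @param alpha intercept.
#' @param term_values list of numeric n-vectors (may be empty).
#' @return numeric n-vector on the link scale.
#' @export
linear_predictor <- function(spec, alpha, term_values = list()) {
  stopifnot(inherits(spec, "sm_model_spec"))
  eta <- rep(alpha, spec$n)
  if (spec$family != "binomial") eta <- eta + spec$offset
  for (tv in term_values) {
    if (length(tv) != spec$n) stop("term value length does not match n")
    eta <- eta + tv
  }
  eta
}
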