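#' Watanabe-Akaike information criterion
#'
#' \deqn{\mathrm{WAIC} = -2\,(\mathrm{lppd} - p_\mathrm{waic}),} with
#' \eqn{\mathrm{lppd} = \sum_i \log\left(\mathrm{mean}_s\, e^{\ell_{si}}\right)}
#' and \eqn{p_\mathrm{waic} = \sum_i \mathrm{var}_s(\ell_{si})} (sample
#' variance over draws), computed with log-sum-exp stabilization. Lower is
#' better.
#'
#' @param loglik draws x n pointwise log-likelihood matrix, or an
#'   `sm_posterior` object.
#' @return scalar WAIC with attributes `lppd` and `p_waic`.
#' @export
waic <- function(loglik) {
  if (inherits(loglik, "sm_posterior")) loglik <- loglik$loglik
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2L) stop("WAIC needs at least 2 draws")
  if (any(!is.finite(loglik))) stop("non-finite entries in the log-likelihood matrix")
  S <- nrow(loglik)
  lppd <- sum(apply(loglik, 2L, logsumexp) - log(S))
  p_waic <- sum(apply(loglik, 2L, stats::var))
  out <- -2 * (lppd - p_waic)
  attr(out, "lppd") <- lppd
  attr(out, "p_waic") <- p_waic
  out
}

#' Mean absolute error of the posterior-mean fit
#'
#' \eqn{\mathrm{MAE} = \frac1n \sum_i |y_i - \hat y_i|}, where
#' \eqn{\hat y_i} is the posterior mean of the mean function \eqn{E(y_i)}.
#'
#' @param samples `sm_posterior`.
#' @param observed observed counts (defaults to the fitted data).
#' @return scalar MAE.
#' @export
mae <- function(samples, observed = samples$y) {
  yhat <- colMeans(fitted_mean(samples))
  mean(abs(observed - yhat))
}

#' Variance decomposition of the random terms
#'
#' Quantifies the relative contribution of each spatial structure: for each
#' retained draw, the population variance (divide by n) over areas of each
#' random term is divided by the variance of the elementwise sum of all
#' random terms — the three-term analogue of var(u)/var(u + v). Proportions
#' are summarized by their posterior mean and equal-tailed 95\% credible
#' interval. Draws in which the total variance is exactly zero are dropped
#' with a message. Because the denominator is the variance of the sum,
#' per-draw proportions can exceed 1 under negative correlation between
#' terms; they are reported as computed.
#'
#' @param samples `sm_posterior`, or a named list of draws x n matrices
#'   (one per random term) for direct use.
#' @param term_labels which terms to report (default: all random terms).
#' @return data.frame of class `sm_var_decomp` with columns `term`, `mean`,
#'   `lo95`, `hi95`; per-draw proportions in `attr(, "draws")`.
#' @export
variance_proportion <- function(samples, term_labels = NULL) {
  fields <- if (inherits(samples, "sm_posterior")) term_fields(samples)
            else lapply(samples, function(m)
              if (is.null(dim(m))) matrix(m, nrow = 1L) else as.matrix(m))
  if (is.null(term_labels)) term_labels <- names(fields)
  missing_terms <- setdiff(term_labels, names(fields))
  if (length(missing_terms))
    stop("terms not present in the model: ", paste(missing_terms, collapse = ", "))
  total <- Reduce(`+`, fields)
  var_total <- apply(total, 1L, pop_var)
  keep <- var_total > 0
  if (!all(keep))
    message(sprintf("dropped %d draw(s) with zero total random-term variance",
                    sum(!keep)))
  if (!any(keep)) stop("all draws have zero total random-term variance")
  prop <- sapply(term_labels, function(lab) {
    apply(fields[[lab]][keep, , drop = FALSE], 1L, pop_var) / var_total[keep]
  })
  prop <- matrix(prop, ncol = length(term_labels),
                 dimnames = list(NULL, term_labels))
  out <- data.frame(
    term = term_labels,
    mean = colMeans(prop),
    lo95 = apply(prop, 2L, stats::quantile, 0.025),
    hi95 = apply(prop, 2L, stats::quantile, 0.975),
    row.names = NULL)
  attr(out, "draws") <- prop
  attr(out, "dropped") <- sum(!keep)
  class(out) <- c("sm_var_decomp", class(out))
  out
}

#' @export
print.sm_var_decomp <- function(x, ...) {
  cat("Random-term variance decomposition (posterior mean [95% CI]):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", x$term[i], x$mean[i],
                x$lo95[i], x$hi95[i]))
  invisible(x)
}

#' Write a variance decomposition as JSON
#' @param decomp `sm_var_decomp`.
#' @param path output path.
#' @export
write_decomposition_json <- function(decomp, path) {
  obj <- stats::setNames(lapply(seq_len(nrow(decomp)), function(i)
    list(mean = decomp$mean[i], lo95 = decomp$lo95[i], hi95 = decomp$hi95[i])),
    decomp$term)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Moran's I spatial autocorrelation
#'
#' Classic cross-product statistic over a binary weight matrix; used in
#' tests to check that simulated fields with and without spatial structure
#' behave as expected.
#'
#' @param x numeric vector.
#' @param W binary symmetric weight matrix.
#' @return scalar Moran's I.
#' @export
morans_i <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}
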