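#' @keywords internal
"_PACKAGE"

# Population variance (divide by n), the convention used throughout the
# variance decomposition so that per-draw proportions are reproducible.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Connected components of a symmetric binary adjacency matrix, by BFS.
# Returns an integer vector of component labels (1-based).
connected_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(W[i, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Derive a stream of child seeds from one top-level seed (counter scheme).
# Kept strictly below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n, stream = 0L) {
  base <- (as.numeric(seed) * 69069 + as.numeric(stream) * 1234567) %% 2147483399
  as.integer((base + seq_len(n) * 104729) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
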