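# Posterior sampling: Hamiltonian Monte Carlo over the latent Gaussian block
# (intercept, spline coefficients, iid effects, or the BYM2 block including
# its transformed hyperparameters), alternated with conjugate Gibbs draws of
# the smoothing precisions (lambda0, lambda1 per surface) and the iid
# precision. Warmup adapts the step size (dual averaging, target acceptance
# 0.8) and a diagonal mass matrix from early-warmup draws.

## ---- family likelihoods -------------------------------------------------

family_ll <- function(engine, eta, logpsi = NULL) {
  y <- engine$y
  switch(engine$family,
    poisson = {
      mu <- exp(eta)
      list(ll = sum(stats::dpois(y, mu, log = TRUE)), deta = y - mu,
           dlogpsi = NULL)
    },
    negbin = {
      # extreme leapfrog states (psi or mu overflowing) are rejected via a
      # non-finite lp; suppress the NaN warnings they would emit
      suppressWarnings({
        psi <- exp(logpsi)
        mu <- exp(eta)
        ll <- sum(stats::dnbinom(y, size = psi, mu = mu, log = TRUE))
        deta <- (y - mu) * psi / (mu + psi)
        dlp <- psi * sum(digamma(y + psi) - digamma(psi) +
                           log(psi / (psi + mu)) + 1 - (y + psi) / (psi + mu))
      })
      list(ll = ll, deta = deta, dlogpsi = dlp)
    },
    binomial = {
      p <- stats::plogis(eta)
      list(ll = sum(stats::dbinom(y, engine$trials, p, log = TRUE)),
           deta = y - engine$trials * p, dlogpsi = NULL)
    })
}

family_pointwise <- function(engine, eta, logpsi = NULL) {
  switch(engine$family,
    poisson = stats::dpois(engine$y, exp(eta), log = TRUE),
    negbin = stats::dnbinom(engine$y, size = exp(logpsi), mu = exp(eta),
                            log = TRUE),
    binomial = stats::dbinom(engine$y, engine$trials, stats::plogis(eta),
                             log = TRUE))
}

## ---- engine construction ------------------------------------------------

build_engine <- function(spec, y) {
  n <- spec$n
  if (length(y) != n) stop("length(y) does not match the model spec")
  if (spec$family != "binomial" && any(y < 0 | y != floor(y)))
    stop("counts must be non-negative integers")
  eng <- list(spec = spec, family = spec$family, y = as.numeric(y), n = n,
              offset = spec$offset, trials = spec$trials,
              priors = spec$priors)
  pr <- spec$priors

  if (spec$comparator == "bym2") {
    W <- spec$adjacency
    Q <- icar_precision(W)
    comp <- connected_components(W)
    sizes <- tabulate(comp)
    islands <- which(sizes[comp] == 1L)
    if (length(islands))
      warning(sprintf("%d island(s) receive independent N(0,1) structured effects",
                      length(islands)))
    sf <- bym2_scaling_factor(W)
    Qs <- sf * Q
    if (length(islands)) {
      Qs[islands, ] <- 0
      Qs[, islands] <- 0
    }
    comps <- lapply(which(sizes > 1L), function(cc) which(comp == cc))
    eng$bym2 <- list(Qs = Qs, comps = comps, islands = islands,
                     constraint_sd = vapply(comps, function(ix) 0.001 * length(ix), 0))
    p <- 1L + 2L * n + 2L
    nm <- c("alpha", paste0("u_star[", seq_len(n), "]"),
            paste0("v_star[", seq_len(n), "]"), "logit_phi", "log_tau")
    eng$idx <- list(alpha = 1L, u = 1L + seq_len(n), w = 1L + n + seq_len(n),
                    lphi = 2L * n + 2L, ltau = 2L * n + 3L)
    eng$kind <- "bym2"
  } else {
    m <- length(spec$smooth_terms)
    idx_beta <- list()
    pos <- 1L
    nm <- "alpha"
    for (k in seq_len(m)) {
      b <- spec$smooth_terms[[k]]
      idx_beta[[k]] <- pos + seq_len(b$ncoef)
      nm <- c(nm, paste0("beta_", names(spec$smooth_terms)[k],
                         "[", seq_len(b$ncoef), "]"))
      pos <- pos + b$ncoef
    }
    idx_v <- NULL
    if (spec$include_iid) {
      idx_v <- pos + seq_len(n)
      nm <- c(nm, paste0("v[", seq_len(n), "]"))
      pos <- pos + n
    }
    p <- pos
    eng$idx <- list(alpha = 1L, beta = idx_beta, v = idx_v)
    eng$kind <- "spline"
  }
  if (spec$family == "negbin") {
    p <- p + 1L
    nm <- c(nm, "log_psi")
    eng$idx$logpsi <- p
  }
  eng$p <- p
  eng$par_names <- nm
  eng
}

engine_hyp_init <- function(eng) {
  if (eng$kind != "spline") return(numeric(0))
  m <- length(eng$spec$smooth_terms)
  h <- c(if (m) rep(1, 2L * m),
         if (!is.null(eng$idx$v)) 20)
  nms <- c(if (m) as.vector(rbind(paste0("lambda0_", names(eng$spec$smooth_terms)),
                                  paste0("lambda1_", names(eng$spec$smooth_terms)))),
           if (!is.null(eng$idx$v)) "tau_v")
  stats::setNames(h, nms)
}

engine_init <- function(eng, jitter_sd = 0) {
  theta <- numeric(eng$p)
  if (eng$family == "binomial") {
    theta[1L] <- stats::qlogis((sum(eng$y) + 0.5) / (sum(eng$trials) + 1))
  } else {
    theta[1L] <- log((sum(eng$y) + 0.5) / sum(exp(eng$offset)))
  }
  if (eng$kind == "bym2") {
    theta[eng$idx$lphi] <- 0    # phi = 0.5
    theta[eng$idx$ltau] <- 0    # tau = 1
    theta[c(eng$idx$u, eng$idx$w)] <- stats::rnorm(2L * eng$n, 0, 0.1)
  } else if (!is.null(eng$idx$v)) {
    theta[eng$idx$v] <- stats::rnorm(eng$n, 0, 0.2)
  }
  if (!is.null(eng$idx$logpsi)) theta[eng$idx$logpsi] <- log(5)
  if (jitter_sd > 0) theta <- theta + stats::rnorm(eng$p, 0, jitter_sd)
  theta
}

engine_eta <- function(eng, theta) {
  eta <- rep(theta[1L], eng$n)
  if (eng$family != "binomial") eta <- eta + eng$offset
  if (eng$kind == "bym2") {
    phi <- stats::plogis(theta[eng$idx$lphi])
    tau <- exp(theta[eng$idx$ltau])
    # no validation here: extreme leapfrog states must yield a non-finite
    # log posterior (rejected) rather than an error
    eta + (sqrt(phi) * theta[eng$idx$u] +
             sqrt(1 - phi) * theta[eng$idx$w]) / sqrt(tau)
  } else {
    for (k in seq_along(eng$idx$beta)) {
      eta <- eta + drop(eng$spec$smooth_terms[[k]]$X %*% theta[eng$idx$beta[[k]]])
    }
    if (!is.null(eng$idx$v)) eta <- eta + theta[eng$idx$v]
    eta
  }
}

# joint log posterior (up to hyperparameter-only constants) and gradient
engine_lp_grad <- function(eng, theta, hyp) {
  pr <- eng$priors
  logpsi <- if (!is.null(eng$idx$logpsi)) theta[eng$idx$logpsi] else NULL
  eta <- engine_eta(eng, theta)
  if (any(!is.finite(eta))) return(list(lp = -Inf, grad = NULL))
  fam <- family_ll(eng, eta, logpsi)
  if (!is.finite(fam$ll)) return(list(lp = -Inf, grad = NULL))
  lp <- fam$ll
  g <- numeric(eng$p)
  alpha <- theta[1L]
  lp <- lp - 0.5 * alpha^2 / pr$alpha_sd^2
  g[1L] <- sum(fam$deta) - alpha / pr$alpha_sd^2

  if (eng$kind == "bym2") {
    u <- theta[eng$idx$u]; w <- theta[eng$idx$w]
    phi <- stats::plogis(theta[eng$idx$lphi])
    tau <- exp(theta[eng$idx$ltau])
    su <- sqrt(phi / tau); sw <- sqrt((1 - phi) / tau)
    S <- su * u + sw * w
    Qu <- drop(eng$bym2$Qs %*% u)
    lp <- lp - 0.5 * sum(u * Qu) - 0.5 * sum(w^2)
    gu <- su * fam$deta - Qu
    if (length(eng$bym2$islands)) {
      isl <- eng$bym2$islands
      lp <- lp - 0.5 * sum(u[isl]^2)
      gu[isl] <- gu[isl] - u[isl]
    }
    for (ci in seq_along(eng$bym2$comps)) {
      ix <- eng$bym2$comps[[ci]]
      sdc <- eng$bym2$constraint_sd[ci]
      s <- sum(u[ix])
      lp <- lp - 0.5 * (s / sdc)^2
      gu[ix] <- gu[ix] - s / sdc^2
    }
    g[eng$idx$u] <- gu
    g[eng$idx$w] <- sw * fam$deta - w
    # phi ~ U(0,1) on the logit scale (Jacobian), tau ~ Gamma on the log scale
    dS_dlphi <- 0.5 * (sqrt(phi) * (1 - phi) * u -
                         phi * sqrt(1 - phi) * w) / sqrt(tau)
    lp <- lp + log(phi) + log1p(-phi)
    g[eng$idx$lphi] <- sum(fam$deta * dS_dlphi) + (1 - 2 * phi)
    lp <- lp + pr$tau_shape * theta[eng$idx$ltau] - pr$tau_rate * tau
    g[eng$idx$ltau] <- sum(fam$deta * (-S / 2)) +
      pr$tau_shape - pr$tau_rate * tau
  } else {
    for (k in seq_along(eng$idx$beta)) {
      b <- eng$spec$smooth_terms[[k]]
      bet <- theta[eng$idx$beta[[k]]]
      Pk <- hyp[[paste0("lambda0_", names(eng$spec$smooth_terms)[k])]] * b$P0 +
        hyp[[paste0("lambda1_", names(eng$spec$smooth_terms)[k])]] * b$P1
      Pb <- drop(Pk %*% bet)
      lp <- lp - 0.5 * sum(bet * Pb)
      g[eng$idx$beta[[k]]] <- drop(crossprod(b$X, fam$deta)) - Pb
    }
    if (!is.null(eng$idx$v)) {
      v <- theta[eng$idx$v]
      lp <- lp - 0.5 * hyp[["tau_v"]] * sum(v^2)
      g[eng$idx$v] <- fam$deta - hyp[["tau_v"]] * v
    }
  }
  if (!is.null(logpsi)) {
    psi <- exp(logpsi)
    lp <- lp + pr$psi_shape * logpsi - pr$psi_rate * psi
    g[eng$idx$logpsi] <- fam$dlogpsi + pr$psi_shape - pr$psi_rate * psi
  }
  if (!is.finite(lp)) return(list(lp = -Inf, grad = NULL))
  list(lp = lp, grad = g)
}

# conjugate Gibbs draws for the smoothing and iid precisions
engine_gibbs <- function(eng, theta, hyp) {
  if (eng$kind != "spline") return(hyp)
  pr <- eng$priors
  for (k in seq_along(eng$idx$beta)) {
    b <- eng$spec$smooth_terms[[k]]
    lab <- names(eng$spec$smooth_terms)[k]
    bet <- theta[eng$idx$beta[[k]]]
    q1 <- max(drop(bet %*% b$P1 %*% bet), 0)
    q0 <- max(drop(bet %*% b$P0 %*% bet), 0)
    hyp[[paste0("lambda1_", lab)]] <-
      stats::rgamma(1L, pr$lambda_shape + b$rank_P1 / 2, pr$lambda_rate + q1 / 2)
    hyp[[paste0("lambda0_", lab)]] <-
      stats::rgamma(1L, pr$lambda_shape + b$rank_P0 / 2, pr$lambda_rate + q0 / 2)
  }
  if (!is.null(eng$idx$v)) {
    v <- theta[eng$idx$v]
    hyp[["tau_v"]] <- stats::rgamma(1L, pr$tau_v_shape + eng$n / 2,
                                    pr$tau_v_rate + sum(v^2) / 2)
  }
  hyp
}

# Ancillarity-sufficiency ("interweaving") rescaling moves: the centered
# parametrization that makes the lambda/tau Gibbs steps conjugate mixes
# slowly over each random term's overall amplitude, so once per iteration
# each term's coefficients and its precision(s) are rescaled jointly,
# (beta, lambda) -> (s beta, lambda / s^2), by a Metropolis step on log s.
# The Gaussian prior quadratic form is invariant under the map; what
# remains is the likelihood ratio, the gamma hyperprior ratio and the net
# Jacobian/normalization factor (s^-4 for a smooth with two precisions,
# s^-2 for the iid term).
engine_asis <- function(eng, theta, hyp, prop_sd = 0.4) {
  if (eng$kind != "spline") return(list(theta = theta, hyp = hyp))
  pr <- eng$priors
  logpsi <- if (!is.null(eng$idx$logpsi)) theta[eng$idx$logpsi] else NULL
  ll_of <- function(th) family_ll(eng, engine_eta(eng, th), logpsi)$ll
  ll_cur <- ll_of(theta)
  lgam <- function(x, a, b) (a - 1) * log(x) - b * x
  for (k in seq_along(eng$idx$beta)) {
    lab <- names(eng$spec$smooth_terms)[k]
    ls <- stats::rnorm(1L, 0, prop_sd)
    s <- exp(ls)
    th2 <- theta
    th2[eng$idx$beta[[k]]] <- s * theta[eng$idx$beta[[k]]]
    l1 <- hyp[[paste0("lambda1_", lab)]]; l0 <- hyp[[paste0("lambda0_", lab)]]
    ll_new <- ll_of(th2)
    lacc <- ll_new - ll_cur - 4 * ls +
      lgam(l1 / s^2, pr$lambda_shape, pr$lambda_rate) -
      lgam(l1, pr$lambda_shape, pr$lambda_rate) +
      lgam(l0 / s^2, pr$lambda_shape, pr$lambda_rate) -
      lgam(l0, pr$lambda_shape, pr$lambda_rate)
    if (is.finite(lacc) && log(stats::runif(1L)) < lacc) {
      theta <- th2
      hyp[[paste0("lambda1_", lab)]] <- l1 / s^2
      hyp[[paste0("lambda0_", lab)]] <- l0 / s^2
      ll_cur <- ll_new
    }
  }
  if (!is.null(eng$idx$v)) {
    ls <- stats::rnorm(1L, 0, prop_sd)
    s <- exp(ls)
    th2 <- theta
    th2[eng$idx$v] <- s * theta[eng$idx$v]
    tv <- hyp[["tau_v"]]
    ll_new <- ll_of(th2)
    lacc <- ll_new - ll_cur - 2 * ls +
      lgam(tv / s^2, pr$tau_v_shape, pr$tau_v_rate) -
      lgam(tv, pr$tau_v_shape, pr$tau_v_rate)
    if (is.finite(lacc) && log(stats::runif(1L)) < lacc) {
      theta <- th2
      hyp[["tau_v"]] <- tv / s^2
      ll_cur <- ll_new
    }
  }
  list(theta = theta, hyp = hyp)
}

# crude curvature-based diagonal mass for the first warmup phase
engine_mass_init <- function(eng, theta, hyp) {
  m <- rep(1, eng$p)
  eta0 <- engine_eta(eng, theta)
  wts <- switch(eng$family,
    poisson = exp(eta0),
    negbin = {
      psi <- exp(theta[eng$idx$logpsi]); mu <- exp(eta0)
      mu * psi / (mu + psi)
    },
    binomial = {
      p0 <- stats::plogis(eta0)
      eng$trials * p0 * (1 - p0)
    })
  m[1L] <- sum(wts) + 1 / eng$priors$alpha_sd^2
  if (eng$kind == "bym2") {
    phi <- stats::plogis(theta[eng$idx$lphi]); tau <- exp(theta[eng$idx$ltau])
    m[eng$idx$u] <- wts * phi / tau + diag(eng$bym2$Qs) + 1
    m[eng$idx$w] <- wts * (1 - phi) / tau + 1
    m[eng$idx$lphi] <- 1
    m[eng$idx$ltau] <- 1
  } else {
    for (k in seq_along(eng$idx$beta)) {
      b <- eng$spec$smooth_terms[[k]]
      lab <- names(eng$spec$smooth_terms)[k]
      Pk <- hyp[[paste0("lambda0_", lab)]] * b$P0 +
        hyp[[paste0("lambda1_", lab)]] * b$P1
      m[eng$idx$beta[[k]]] <- colSums(b$X^2 * wts) + diag(Pk)
    }
    if (!is.null(eng$idx$v)) m[eng$idx$v] <- wts + hyp[["tau_v"]]
  }
  if (!is.null(eng$idx$logpsi)) m[eng$idx$logpsi] <- max(eng$n / 4, 1)
  pmax(m, 1e-6)
}

## ---- Hamiltonian Monte Carlo with warmup adaptation ---------------------

hmc_chain <- function(eng, iterations, burnin, thin, seed,
                      L_range = c(8L, 16L), target_accept = 0.8,
                      max_init_attempts = 20L) {
  set.seed(seed)
  hyp <- engine_hyp_init(eng)
  theta <- engine_init(eng)
  cur <- engine_lp_grad(eng, theta, hyp)
  att <- 0L
  while (!is.finite(cur$lp) && att < max_init_attempts) {
    att <- att + 1L
    theta <- engine_init(eng, jitter_sd = 0.1)
    cur <- engine_lp_grad(eng, theta, hyp)
  }
  if (!is.finite(cur$lp))
    stop("non-finite log posterior at initial values after repeated attempts")

  p <- eng$p
  mass <- engine_mass_init(eng, theta, hyp)
  eps <- 0.5 / max(p, 4)^0.25

  # dual-averaging state (Hoffman & Gelman defaults)
  da_reset <- function(eps0) list(mu = log(10 * eps0), log_eps = log(eps0),
                                  log_eps_bar = log(eps0), H = 0, t = 0)
  da <- da_reset(eps)
  da_update <- function(da, accept_prob) {
    da$t <- da$t + 1
    w <- 1 / (da$t + 10)
    da$H <- (1 - w) * da$H + w * (target_accept - accept_prob)
    da$log_eps <- da$mu - sqrt(da$t) / 0.05 * da$H
    rho <- da$t^-0.75
    da$log_eps_bar <- rho * da$log_eps + (1 - rho) * da$log_eps_bar
    da
  }

  n_keep <- (iterations - burnin) %/% thin
  draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, eng$par_names))
  hyps <- matrix(NA_real_, n_keep, length(hyp),
                 dimnames = list(NULL, names(hyp)))
  loglik <- matrix(NA_real_, n_keep, eng$n)
  kept <- 0L
  accepted <- 0L

  mwin <- c(floor(burnin * 0.25), floor(burnin * 0.75))
  msamp <- NULL

  for (it in seq_len(iterations)) {
    L <- sample(seq(L_range[1L], L_range[2L]), 1L)
    mom <- stats::rnorm(p, 0, sqrt(mass))
    H0 <- -cur$lp + 0.5 * sum(mom^2 / mass)
    th <- theta
    g <- cur$grad
    mom1 <- mom + 0.5 * eps * g
    ok <- TRUE
    prop <- NULL
    for (s in seq_len(L)) {
      th <- th + eps * mom1 / mass
      prop <- engine_lp_grad(eng, th, hyp)
      if (!is.finite(prop$lp)) { ok <- FALSE; break }
      mom1 <- mom1 + (if (s < L) eps else 0.5 * eps) * prop$grad
    }
    if (ok) {
      H1 <- -prop$lp + 0.5 * sum(mom1^2 / mass)
      a_prob <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    } else a_prob <- 0
    if (stats::runif(1L) < a_prob) {
      theta <- th
      cur <- prop
      accepted <- accepted + 1L
    }

    if (it <= burnin) {
      da <- da_update(da, a_prob)
      eps <- exp(da$log_eps)
      eps <- min(max(eps, 1e-7), 2)
      if (it >= mwin[1L] && it <= mwin[2L]) msamp <- rbind(msamp, theta)
      if (it == mwin[2L] && !is.null(msamp) && nrow(msamp) > 10L) {
        vv <- apply(msamp, 2L, stats::var)
        N <- nrow(msamp)
        vv <- vv * N / (N + 5) + 1e-3 * 5 / (N + 5)
        mass <- 1 / pmax(vv, 1e-8)
        da <- da_reset(exp(da$log_eps_bar))
        eps <- exp(da$log_eps)
      }
      if (it == burnin) eps <- exp(da$log_eps_bar)
    }

    hyp <- engine_gibbs(eng, theta, hyp)
    if (eng$kind == "spline") {
      aw <- engine_asis(eng, theta, hyp)
      theta <- aw$theta
      hyp <- aw$hyp
      hyp <- engine_gibbs(eng, theta, hyp)
      # refresh cached lp/grad: Gibbs and rescaling moved the target
      cur <- engine_lp_grad(eng, theta, hyp)
    }

    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
      if (length(hyp)) hyps[kept, ] <- hyp
      logpsi <- if (!is.null(eng$idx$logpsi)) theta[eng$idx$logpsi] else NULL
      loglik[kept, ] <- family_pointwise(eng, engine_eta(eng, theta), logpsi)
    }
  }
  list(draws = draws, hyp = hyps, loglik = loglik,
       accept_rate = accepted / iterations, eps = eps)
}

## ---- public interface ---------------------------------------------------

#' Sample the posterior of a disease-mapping model
#'
#' Runs `chains` independent MCMC chains (HMC for the latent block, Gibbs
#' for the conjugate smoothing/iid precisions), retaining
#' `chains * (iterations - burnin) / thin` draws together with the
#' pointwise log-likelihood matrix needed for WAIC. Fully reproducible for
#' a fixed `seed` (chain seeds are derived from it by a counter scheme).
#'
#' @param spec [model_spec()] object.
#' @param y observed counts (or successes for the binomial family).
#' @param chains number of chains (default 4).
#' @param iterations iterations per chain (default 2000).
#' @param burnin warmup iterations discarded per chain (default 1000).
#' @param thin thinning interval (default 1).
#' @param seed integer seed (mandatory).
#' @param L_range integer range of leapfrog steps per HMC trajectory
#'   (jittered uniformly); longer trajectories traverse the slow ridge
#'   between competing smooth terms at higher cost per iteration.
#' @return object of class `sm_posterior`.
#' @export
run_mcmc <- function(spec, y, chains = 4L, iterations = 2000L,
                     burnin = 1000L, thin = 1L, seed,
                     L_range = c(8L, 16L)) {
  stopifnot(inherits(spec, "sm_model_spec"))
  if (missing(seed)) stop("a seed is mandatory for reproducible runs")
  if (iterations <= burnin) stop("iterations must exceed burnin")
  eng <- build_engine(spec, y)
  chain_seeds <- derive_seeds(seed, chains)
  res <- lapply(seq_len(chains), function(ch)
    hmc_chain(eng, iterations, burnin, thin, chain_seeds[ch],
              L_range = L_range))
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  hyps <- do.call(rbind, lapply(res, `[[`, "hyp"))
  loglik <- do.call(rbind, lapply(res, `[[`, "loglik"))
  if (any(!is.finite(loglik)))
    warning("non-finite pointwise log-likelihood in retained draws")
  n_keep <- (iterations - burnin) %/% thin
  structure(
    list(draws = draws, hyp = hyps, loglik = loglik,
         chain = rep(seq_len(chains), each = n_keep),
         engine = eng, spec = spec, y = as.numeric(y),
         meta = list(chains = chains, iterations = iterations,
                     burnin = burnin, thin = thin, seed = seed,
                     accept_rate = vapply(res, `[[`, 0, "accept_rate"),
                     step_size = vapply(res, `[[`, 0, "eps"))),
    class = "sm_posterior")
}

#' @export
print.sm_posterior <- function(x, ...) {
  cat(sprintf("<sm_posterior> %s model, %d draws (%d chains), mean accept %.2f\n",
              x$spec$family, nrow(x$draws), x$meta$chains,
              mean(x$meta$accept_rate)))
  invisible(x)
}

#' Per-draw values of each random term
#'
#' Evaluates every random term of the fitted model at the data points for
#' each retained draw: each spline surface (\eqn{X_k \beta_k}), the iid
#' term, or the BYM2 structured/unstructured components.
#'
#' @param samples `sm_posterior`.
#' @return named list of draws x n matrices.
#' @export
term_fields <- function(samples) {
  stopifnot(inherits(samples, "sm_posterior"))
  eng <- samples$engine
  out <- list()
  if (eng$kind == "bym2") {
    phi <- stats::plogis(samples$draws[, eng$idx$lphi])
    tau <- exp(samples$draws[, eng$idx$ltau])
    u <- samples$draws[, eng$idx$u, drop = FALSE]
    w <- samples$draws[, eng$idx$w, drop = FALSE]
    out$structured <- u * sqrt(phi / tau)
    out$unstructured <- w * sqrt((1 - phi) / tau)
  } else {
    for (k in seq_along(eng$idx$beta)) {
      lab <- names(eng$spec$smooth_terms)[k]
      out[[lab]] <- samples$draws[, eng$idx$beta[[k]], drop = FALSE] %*%
        t(eng$spec$smooth_terms[[k]]$X)
    }
    if (!is.null(eng$idx$v))
      out$iid <- samples$draws[, eng$idx$v, drop = FALSE]
  }
  out
}

#' Per-draw fitted mean E(y_i)
#' @param samples `sm_posterior`.
#' @return draws x n matrix of mean-function values.
#' @export
fitted_mean <- function(samples) {
  eng <- samples$engine
  eta <- t(apply(samples$draws, 1L, function(th) engine_eta(eng, th)))
  if (eng$family == "binomial") eng$trials * stats::plogis(eta) else exp(eta)
}

#' Split-chain potential scale reduction factor
#'
#' Standard split-R-hat: each chain is halved, and between/within half-chain
#' variances are compared.
#'
#' @param samples `sm_posterior`.
#' @param pars parameter names (default `"alpha"`).
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(samples, pars = "alpha") {
  stopifnot(inherits(samples, "sm_posterior"))
  vapply(pars, function(pn) {
    x <- samples$draws[, pn]
    halves <- list()
    for (ch in unique(samples$chain)) {
      xc <- x[samples$chain == ch]
      h <- length(xc) %/% 2L
      halves <- c(halves, list(xc[seq_len(h)], xc[h + seq_len(h)]))
    }
    m <- length(halves); nn <- length(halves[[1L]])
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    B <- nn * stats::var(means)
    Wv <- mean(vars)
    if (Wv == 0) return(1)
    sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
  }, 0)
}

#' Export posterior draws as a tidy table
#'
#' Long format: one row per (draw, chain, parameter) triple, including the
#' Gibbs-sampled hyperparameters.
#'
#' @param samples `sm_posterior`.
#' @param path optional CSV path; if supplied the table is written there.
#' @return data.frame (invisibly when written to file).
#' @export
posterior_tidy <- function(samples, path = NULL) {
  nk <- nrow(samples$draws) / samples$meta$chains
  all <- cbind(samples$draws, samples$hyp)
  d <- data.frame(
    draw = rep(rep(seq_len(nk), times = samples$meta$chains), ncol(all)),
    chain = rep(samples$chain, ncol(all)),
    parameter = rep(colnames(all), each = nrow(all)),
    value = as.vector(all))
  if (!is.null(path)) {
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(d))
  }
  d
}
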