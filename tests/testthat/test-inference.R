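test_that("WAIC matches hand arithmetic and the naive oracle", {
  # all draws identical: zero penalty
  ll <- rbind(c(-1, -2.5), c(-1, -2.5))
  expect_equal(as.numeric(waic(ll)), -2 * (-1 - 2.5))
  expect_equal(attr(waic(ll), "p_waic"), 0)
  # 2 draws, 1 observation
  ll2 <- matrix(c(-1, -2), ncol = 1)
  w <- waic(ll2)
  expect_equal(attr(w, "lppd"), log((exp(-1) + exp(-2)) / 2))
  expect_equal(attr(w, "p_waic"), 0.5)
  expect_equal(as.numeric(w), -2 * (log((exp(-1) + exp(-2)) / 2) - 0.5))
  # brute-force agreement on random matrices
  set.seed(40)
  for (r in 1:5) {
    m <- matrix(rnorm(60, -2, 1), 10, 6)
    expect_equal(as.numeric(waic(m)), naive_waic(m), tolerance = 1e-10)
  }
  expect_error(waic(matrix(c(-1, NA), 2, 1)), "at least 2|non-finite")
  expect_error(waic(rbind(c(-1, Inf), c(-2, -3))), "non-finite")
})

test_that("variance proportions follow the population-variance arithmetic", {
  # single draw, u = (1,-1,0), v = (2,-2,0): prop(u) = (2/3)/6 = 1/9
  d <- variance_proportion(list(u = rbind(c(1, -1, 0)), v = rbind(c(2, -2, 0))))
  expect_equal(d$mean[d$term == "u"], 1 / 9)
  expect_equal(d$mean[d$term == "v"], 4 / 9)
  # v identically zero: prop(u) = 1 in every draw
  d2 <- variance_proportion(list(u = rbind(c(1, 2, 4), c(0, 1, 3)),
                                 v = matrix(0, 2, 3)))
  expect_equal(d2$mean[d2$term == "u"], 1)
  expect_equal(d2$mean[d2$term == "v"], 0)
  expect_equal(d2$lo95, c(1, 0), ignore_attr = TRUE)
  # zero-total-variance draws are dropped with a message
  expect_message(
    d3 <- variance_proportion(list(u = rbind(c(1, -1), c(0, 0)),
                                   v = rbind(c(0, 0), c(0, 0)))),
    "dropped 1")
  expect_equal(d3$mean[1], 1)
  expect_error(variance_proportion(list(u = matrix(0, 2, 2),
                                        v = matrix(0, 2, 2))), "zero total")
})

test_that("intercept-only Poisson model matches the Gamma-Poisson oracle", {
  spec <- model_spec("poisson", offset = log(c(1, 1)), include_iid = FALSE)
  post <- run_mcmc(spec, c(3L, 5L), chains = 2, iterations = 3000,
                   burnin = 500, seed = 77)
  # flat-ish prior: posterior of exp(alpha) ~ Gamma(8 + eps, 2); mean ~ 4
  rate_draws <- exp(post$draws[, "alpha"])
  expect_equal(mean(rate_draws), 4, tolerance = 0.4)
  # retained-draw bookkeeping
  expect_equal(nrow(post$draws), 2 * (3000 - 500))
  expect_equal(dim(post$loglik), c(5000, 2))
  expect_true(all(is.finite(post$loglik)))
  # determinism: identical runs are bit-identical
  post2 <- run_mcmc(spec, c(3L, 5L), chains = 2, iterations = 3000,
                    burnin = 500, seed = 77)
  expect_identical(post$draws, post2$draws)
  # unequal offsets: posterior mean of alpha near log(sum y / sum xi)
  spec3 <- model_spec("poisson", offset = log(c(2, 5, 1, 4)),
                      include_iid = FALSE)
  post3 <- run_mcmc(spec3, c(7L, 14L, 3L, 11L), chains = 2,
                    iterations = 3000, burnin = 500, seed = 78)
  expect_equal(mean(post3$draws[, "alpha"]), log(35 / 12), tolerance = 0.15)
})

test_that("chains converge on a well-specified instance and thinning works", {
  set.seed(41)
  n <- 60
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rep(1e6, n))   # informative counts
  coords <- scale_coordinates(cents)
  sim <- single_source(geog, coords, phi = 1, seed = 17)
  basis <- build_tprs_basis(coords, K = 12, label = "distance")
  spec <- model_spec("poisson", offset = sim$offset,
                     smooth_terms = list(distance = basis))
  post <- run_mcmc(spec, sim$y, chains = 4, iterations = 1200, burnin = 600,
                   thin = 3, seed = 79)
  expect_equal(nrow(post$draws), 4 * 200)
  expect_lt(rhat(post, "alpha"), 1.02)
  expect_true(all(post$meta$accept_rate > 0.5))
  # alpha recovered near its true value 0
  expect_lt(abs(mean(post$draws[, "alpha"])), 0.15)
})

test_that("MAE is the mean absolute residual of the posterior-mean fit", {
  spec <- model_spec("poisson", offset = log(c(1, 1)), include_iid = FALSE)
  post <- run_mcmc(spec, c(3L, 5L), chains = 1, iterations = 800,
                   burnin = 200, seed = 80)
  mu <- fitted_mean(post)
  expect_equal(mae(post), mean(abs(c(3, 5) - colMeans(mu))))
  expect_equal(mae(post, observed = colMeans(mu)), 0, tolerance = 1e-12)
  # hand case on supplied observations
  expect_equal(mean(abs(c(0, 2) - c(1, 1))), 1)
})

test_that("negative binomial with large dispersion approaches the Poisson fit", {
  set.seed(42)
  n <- 40
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rep(5e5, n))
  coords <- scale_coordinates(cents)
  sim <- single_source(geog, coords, phi = 1, seed = 18)
  spec_p <- model_spec("poisson", offset = sim$offset, include_iid = FALSE)
  spec_nb <- model_spec("negbin", offset = sim$offset, include_iid = FALSE,
                        priors = list(psi_shape = 200, psi_rate = 1))
  post_p <- run_mcmc(spec_p, sim$y, chains = 2, iterations = 1500,
                     burnin = 500, seed = 81)
  post_nb <- run_mcmc(spec_nb, sim$y, chains = 2, iterations = 1500,
                      burnin = 500, seed = 81)
  # dispersion prior concentrated on psi ~ 200: near-Poisson variance
  mu_p <- colMeans(fitted_mean(post_p))
  mu_nb <- colMeans(fitted_mean(post_nb))
  expect_lt(max(abs(mu_p - mu_nb) / mu_p), 0.1)
})

test_that("the BYM2 comparator runs and its mixing parameter tracks the truth direction", {
  syn <- synthetic_geography(100, seed = 19)
  geog <- syn$geography
  coords <- scale_coordinates(geog$centroids)
  sim1 <- single_source(geog, coords, phi = 1, seed = 20)
  spec <- model_spec("poisson", offset = sim1$offset, comparator = "bym2",
                     adjacency = geog$adjacency)
  post1 <- run_mcmc(spec, sim1$y, chains = 2, iterations = 1500, burnin = 700,
                    seed = 82)
  phi1 <- mean(stats::plogis(post1$draws[, "logit_phi"]))
  sim0 <- single_source(geog, coords, phi = 0, seed = 20)
  post0 <- run_mcmc(spec, sim0$y, chains = 2, iterations = 1500, burnin = 700,
                    seed = 82)
  phi0 <- mean(stats::plogis(post0$draws[, "logit_phi"]))
  expect_gt(phi1, phi0)
  dec <- variance_proportion(post1)
  expect_setequal(dec$term, c("structured", "unstructured"))
})

test_that("WAIC prefers the spline model on spatially structured data", {
  syn <- synthetic_geography(100, seed = 23)
  geog <- syn$geography
  coords <- scale_coordinates(geog$centroids)
  sim <- single_source(geog, coords, phi = 1, seed = 24)
  basis <- build_tprs_basis(coords, K = 20, label = "distance")
  spec_s <- model_spec("poisson", offset = sim$offset,
                       smooth_terms = list(distance = basis))
  spec_0 <- model_spec("poisson", offset = sim$offset, include_iid = FALSE)
  post_s <- run_mcmc(spec_s, sim$y, chains = 2, iterations = 1500,
                     burnin = 700, seed = 83)
  post_0 <- run_mcmc(spec_0, sim$y, chains = 2, iterations = 1500,
                     burnin = 700, seed = 83)
  expect_lt(as.numeric(waic(post_s)), as.numeric(waic(post_0)))
})

test_that("binomial models fit binary outcomes", {
  set.seed(43)
  n <- 80
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rep(2e4, n))
  coords <- scale_coordinates(cents)
  sim <- binary_outcome(geog, coords, phi = 0.5, seed = 25)
  spec <- model_spec("binomial", trials = rep(1L, n), include_iid = FALSE,
                     smooth_terms = list(
                       distance = build_tprs_basis(coords, K = 10,
                                                   label = "distance")))
  post <- run_mcmc(spec, sim$y, chains = 2, iterations = 1200, burnin = 600,
                   seed = 84)
  expect_true(all(is.finite(post$loglik)))
  expect_lt(abs(mean(post$draws[, "alpha"])), 1)
  expect_true(all(fitted_mean(post) >= 0 & fitted_mean(post) <= 1))
})

test_that("posterior draws export tidily", {
  spec <- model_spec("poisson", offset = log(c(1, 2)), include_iid = FALSE)
  post <- run_mcmc(spec, c(2L, 4L), chains = 2, iterations = 400,
                   burnin = 200, seed = 85)
  d <- posterior_tidy(post)
  expect_setequal(unique(d$parameter), "alpha")
  expect_equal(nrow(d), 400)
  path <- tempfile(fileext = ".csv")
  posterior_tidy(post, path)
  expect_equal(nrow(utils::read.csv(path)), 400)
})
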