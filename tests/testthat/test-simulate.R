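test_that("the bimodal test surface evaluates to its closed-form values", {
  # frozen from direct arithmetic: pi*0.3*0.4*(1.2 + 0.8*exp(-0.25/0.09 - 0.25/0.16))
  expect_equal(sm_surface(0.2, 0.3), 0.4563200, tolerance = 1e-6)
  expect_equal(sm_surface(0.7, 0.8), 0.3074888, tolerance = 1e-6)
  set.seed(30)
  expect_true(all(sm_surface(runif(100), runif(100)) > 0))
})

test_that("centre_field subtracts the mean and is idempotent", {
  expect_equal(centre_field(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(-1, 0.5, 0.5)
  expect_equal(centre_field(x), x)
  set.seed(31)
  expect_lt(abs(mean(centre_field(rnorm(50, 5)))), 1e-14)
})

test_that("single_source hits its boundary cases and is seed-reproducible", {
  syn <- synthetic_geography(80, seed = 7)
  geog <- syn$geography
  coords <- scale_coordinates(geog$centroids)
  s1 <- single_source(geog, coords, phi = 1, seed = 5)
  # phi = 1: S equals the standardized smooth exactly, unit variance
  expect_equal(s1$true_S, s1$true_smooths$smooth)
  expect_equal(mean(s1$true_S), 0)
  expect_equal(mean(s1$true_S^2), 1, tolerance = 1e-12)
  expect_gt(morans_i(s1$true_S, geog$adjacency), 0.2)
  # phi = 0: pure N(0,1) noise, negligible spatial autocorrelation
  s0 <- single_source(geog, coords, phi = 0, seed = 5)
  expect_lt(abs(morans_i(s0$true_S, geog$adjacency)), 0.25)
  # determinism
  expect_identical(single_source(geog, coords, 0.5, seed = 9)$y,
                   single_source(geog, coords, 0.5, seed = 9)$y)
  expect_error(single_source(geog, coords, 1.3, seed = 1), "phi")
})

test_that("counts have the stated Poisson mean structure", {
  # large-n Monte-Carlo oracle: y / (xi * exp(S)) averages to 1
  set.seed(32)
  n <- 5000
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rlnorm(n, log(2e4), 1))
  coords <- scale_coordinates(cents)
  sim <- single_source(geog, coords, phi = 1, seed = 6)
  xi <- geog$populations / 1e5
  expect_equal(mean(sim$y / (xi * exp(sim$true_S))), 1, tolerance = 0.05)
  expect_true(all(sim$y >= 0) && all(sim$y == floor(sim$y)))
  expect_equal(sim$offset, log(xi))
})

test_that("noise realizations have unit empirical variance at phi = 0", {
  set.seed(33)
  n <- 4000
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rep(2e4, n))
  sim <- single_source(geog, scale_coordinates(cents), phi = 0, seed = 8)
  expect_equal(var(sim$true_S), 1, tolerance = 0.06)
})

test_that("two_source reduces, validates and swaps as expected", {
  syn <- synthetic_geography(80, seed = 7)
  geog <- syn$geography
  cd <- scale_coordinates(geog$centroids, "distance")
  cm <- movement_coordinates(syn$flows)
  # degenerate reduction to a pure single-source field
  t1 <- two_source(geog, cd, cm, 1, 0, 0, seed = 11)
  s1 <- single_source(geog, cd, phi = 1, seed = 11)
  expect_equal(t1$true_S, s1$true_S)
  expect_identical(t1$y, s1$y)
  # swapping the coordinate systems swaps the smooth fields
  t2 <- two_source(geog, cd, cm, 0.3, 0.6, 0.1, seed = 12)
  t3 <- two_source(geog, cm, cd, 0.6, 0.3, 0.1, seed = 12)
  expect_equal(t2$true_smooths$distance, t3$true_smooths$movement)
  expect_equal(t2$true_S, t3$true_S)
  expect_error(two_source(geog, cd, cm, 0.5, 0.4, 0.2, seed = 1), "sum to 1")
})

test_that("scenario grids enumerate the stated configurations deterministically", {
  g1 <- single_source_grid(99)
  expect_equal(nrow(g1), 11)
  expect_equal(g1$phi, seq(0, 1, 0.1))
  g2 <- two_source_grid(99)
  expect_equal(nrow(g2), 10)
  expect_equal(g2$phi1, seq(0, 0.9, 0.1))
  expect_equal(g2$phi2, 0.9 - g2$phi1)
  expect_true(all(g2$phi3 == 0.1))
  expect_equal(g2$phi1 + g2$phi2 + g2$phi3, rep(1, 10))
  expect_identical(single_source_grid(99), single_source_grid(99))
  expect_false(all(single_source_grid(100)$seed == g1$seed))
})

test_that("binary outcomes follow the logistic model", {
  set.seed(34)
  n <- 5000
  cents <- cbind(runif(n), runif(n))
  geog <- geography(seq_len(n), cents, rep(2e4, n))
  coords <- scale_coordinates(cents)
  sim <- binary_outcome(geog, coords, phi = 0, seed = 13, alpha = -2)
  expect_true(all(sim$y %in% c(0, 1)))
  # independent Monte-Carlo oracle for E[plogis(-2 + eps)]
  oracle <- mean(stats::plogis(-2 + rnorm(2e5)))
  expect_equal(mean(sim$y), oracle, tolerance = 0.02)
  # phi = 1: spatially clustered successes
  syn <- synthetic_geography(200, seed = 14)
  cb <- scale_coordinates(syn$geography$centroids)
  simc <- binary_outcome(syn$geography, cb, phi = 1, seed = 15)
  expect_gt(morans_i(simc$y, syn$geography$adjacency), 0)
})

test_that("synthetic geography is reproducible, connected and log-spread", {
  a <- synthetic_geography(60, seed = 3)
  b <- synthetic_geography(60, seed = 3)
  expect_identical(a$geography$centroids, b$geography$centroids)
  expect_identical(a$geography$populations, b$geography$populations)
  expect_identical(unclass(a$flows), unclass(b$flows))
  for (sd in c(3, 4, 5)) {
    g <- synthetic_geography(50, seed = sd)$geography
    comp <- splinemap:::connected_components(g$adjacency)
    expect_equal(max(comp), 1)              # Delaunay graph is connected
  }
  big <- synthetic_geography(400, seed = 5)$geography
  expect_gt(log10(max(big$populations) / min(big$populations)), 2)
  expect_error(synthetic_geography(5, seed = 1), "at least 10")
})

test_that("simulated datasets round-trip through CSV", {
  syn <- synthetic_geography(30, seed = 8)
  sim <- single_source(syn$geography, scale_coordinates(syn$geography$centroids),
                       0.5, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_simulated_csv(sim, path)
  d <- read_area_data_csv(path)
  expect_equal(d$count, sim$y)
  expect_equal(d$true_S, sim$true_S, tolerance = 1e-12)
  expect_equal(d$true_smooth_smooth, sim$true_smooths$smooth, tolerance = 1e-12)
})
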