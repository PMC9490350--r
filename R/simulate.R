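# Data-generating processes with known mixing parameters, plus a synthetic
# geography generator so the whole framework is testable without any
# external download.

#' Bimodal test surface on the unit square
#'
#' The smooth test function used by the simulation scenarios: a sum of two
#' Gaussian bumps,
#' \deqn{sm(x, z) = \pi\sigma_x\sigma_z\left(1.2\,
#'   e^{-(x-0.2)^2/\sigma_x^2 - (z-0.3)^2/\sigma_z^2} +
#'   0.8\, e^{-(x-0.7)^2/\sigma_x^2 - (z-0.8)^2/\sigma_z^2}\right),}
#' with \eqn{\sigma_x = 0.3}, \eqn{\sigma_z = 0.4}. Strictly positive
#' everywhere; vectorized in both arguments.
#'
#' @param x,z coordinates (used on \[0, 1\]).
#' @param sigma_x,sigma_z bump widths.
#' @return numeric vector of surface values.
#' @export
sm_surface <- function(x, z, sigma_x = 0.3, sigma_z = 0.4) {
  pi * sigma_x * sigma_z *
    (1.2 * exp(-(x - 0.2)^2 / sigma_x^2 - (z - 0.3)^2 / sigma_z^2) +
       0.8 * exp(-(x - 0.7)^2 / sigma_x^2 - (z - 0.8)^2 / sigma_z^2))
}

#' Centre a field at zero
#'
#' Subtracts the overall mean so the field averages exactly to zero across
#' areas. Idempotent.
#'
#' @param values numeric vector.
#' @return centred vector.
#' @export
centre_field <- function(values) values - mean(values)

# Centre and scale a field to unit population variance across areas. The
# mixing parameters weight the smooth field against unit-variance N(0,1)
# noise; standardizing puts both components on the same scale, which is
# what makes the mixing parameter a variance share (see the methods
# vignette for the rationale).
standardize_field <- function(values) {
  v <- centre_field(values)
  s <- sqrt(pop_var(v))
  if (s == 0) stop("cannot standardize a constant field")
  v / s
}

sim_offsets <- function(geog) log(geog$populations / 1e5)

sim_dataset <- function(geog, S, smooths, config, seed, family = "poisson",
                        alpha = 0) {
  xi <- geog$populations / 1e5
  if (family == "poisson") {
    y <- stats::rpois(length(S), xi * exp(alpha + S))
  } else {
    y <- stats::rbinom(length(S), 1L, stats::plogis(alpha + S))
  }
  structure(
    list(y = y, offset = log(xi), true_S = S, true_smooths = smooths,
         geography = geog, config = config, family = family, seed = seed),
    class = "sm_simulated")
}

#' @export
print.sm_simulated <- function(x, ...) {
  cat(sprintf("<sm_simulated> %s, n = %d, total count %d, config: %s\n",
              x$family, length(x$y), sum(x$y),
              paste(names(x$config), unlist(x$config), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate counts with a single source of spatial structure
#'
#' Generates the spatial term
#' \deqn{S_i = \phi\, \tilde{sm}(x_i, z_i) + (1 - \phi)\, \varepsilon_i,
#'   \qquad \varepsilon_i \sim N(0, 1),}
#' where \eqn{\tilde{sm}} is the bimodal test surface evaluated at the
#' connectivity coordinates, centred and standardized to unit variance
#' across areas so both components are on the scale of the unit-variance
#' noise (making \eqn{\phi} interpretable as the structured variance
#' share; the weights enter linearly, not as square roots). Counts are
#' drawn as \eqn{y_i \sim \mathrm{Poisson}(\xi_i e^{\alpha + S_i})} with
#' \eqn{\xi_i = \mathrm{population}_i / 10^5} and \eqn{\alpha = 0}.
#'
#' @param geog [geography()].
#' @param coords `sm_coords` on the unit square (e.g. scaled centroids).
#' @param phi mixing parameter in \[0, 1\].
#' @param seed integer seed.
#' @param alpha intercept (default 0).
#' @return object of class `sm_simulated`.
#' @export
single_source <- function(geog, coords, phi, seed, alpha = 0) {
  stopifnot_scalar_number(phi, "phi")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  set.seed(seed)
  xy <- coords$coords
  smv <- standardize_field(sm_surface(xy[, 1L], xy[, 2L]))
  eps <- stats::rnorm(nrow(xy))
  S <- phi * smv + (1 - phi) * eps
  sim_dataset(geog, S, list(smooth = smv),
              list(phi = phi, alpha = alpha), seed, "poisson", alpha)
}

#' Simulate counts with two sources of spatial structure
#'
#' \deqn{S_i = \phi_1\, \tilde{sm}(a_i, b_i) + \phi_2\, \tilde{sm}(c_i, d_i)
#'   + \phi_3\, \varepsilon_i, \qquad \phi_1 + \phi_2 + \phi_3 = 1,}
#' with the test surface applied to a distance-based coordinate system
#' \eqn{(a, b)} and a movement-based one \eqn{(c, d)} (both standardized as
#' in [single_source()]).
#'
#' @param geog [geography()].
#' @param coords_distance,coords_movement the two `sm_coords` systems.
#' @param phi1,phi2,phi3 non-negative weights summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @param alpha intercept (default 0).
#' @return `sm_simulated`.
#' @export
two_source <- function(geog, coords_distance, coords_movement,
                       phi1, phi2, phi3, seed, alpha = 0) {
  if (any(c(phi1, phi2, phi3) < 0) || abs(phi1 + phi2 + phi3 - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  set.seed(seed)
  ab <- coords_distance$coords
  cd <- coords_movement$coords
  sm1 <- standardize_field(sm_surface(ab[, 1L], ab[, 2L]))
  sm2 <- standardize_field(sm_surface(cd[, 1L], cd[, 2L]))
  eps <- stats::rnorm(nrow(ab))
  S <- phi1 * sm1 + phi2 * sm2 + phi3 * eps
  sim_dataset(geog, S, list(distance = sm1, movement = sm2),
              list(phi1 = phi1, phi2 = phi2, phi3 = phi3, alpha = alpha),
              seed, "poisson", alpha)
}

#' Simulate a binary outcome with spatial structure
#'
#' \eqn{y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha + S_i))}
#' with \eqn{S_i} built exactly as in [single_source()].
#'
#' @inheritParams single_source
#' @return `sm_simulated` with `family = "bernoulli"`.
#' @export
binary_outcome <- function(geog, coords, phi, seed, alpha = 0) {
  stopifnot_scalar_number(phi, "phi")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  set.seed(seed)
  xy <- coords$coords
  smv <- standardize_field(sm_surface(xy[, 1L], xy[, 2L]))
  eps <- stats::rnorm(nrow(xy))
  S <- phi * smv + (1 - phi) * eps
  sim_dataset(geog, S, list(smooth = smv),
              list(phi = phi, alpha = alpha), seed, "bernoulli", alpha)
}

#' Scenario grids with known mixing parameters
#'
#' `single_source_grid()` returns the 11 single-source configurations
#' (\eqn{\phi} from 0 to 1 in steps of 0.1); `two_source_grid()` the 10
#' two-source configurations (\eqn{\phi_3} fixed at 0.1, \eqn{\phi_1} from
#' 0 to 0.9 in steps of 0.1, \eqn{\phi_2 = 0.9 - \phi_1}). Scenario seeds
#' derive from the top-level seed plus the scenario index.
#'
#' @param seed top-level integer seed.
#' @return data.frame of scenario configurations.
#' @export
single_source_grid <- function(seed) {
  phi <- seq(0, 1, by = 0.1)
  data.frame(scenario = seq_along(phi), phi = phi,
             seed = derive_seeds(seed, length(phi), stream = 1L))
}

#' @rdname single_source_grid
#' @export
two_source_grid <- function(seed) {
  phi1 <- seq(0, 0.9, by = 0.1)
  data.frame(scenario = seq_along(phi1), phi1 = phi1, phi2 = 0.9 - phi1,
             phi3 = 0.1, seed = derive_seeds(seed, length(phi1), stream = 2L))
}

## ---- synthetic geography ------------------------------------------------

# Bowyer-Watson Delaunay triangulation; returns the edge set. O(n^2),
# adequate for desk-scale n. Assumes points in general position (the
# jittered generator guarantees this almost surely).
delaunay_edges <- function(pts) {
  n <- nrow(pts)
  M <- max(abs(pts)) * 10 + 10
  verts <- rbind(pts, c(-3 * M, -3 * M), c(3 * M, -3 * M), c(0, 3 * M))
  super <- n + 1:3
  circum <- function(tri) {
    p <- verts[tri, , drop = FALSE]
    ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
    cx <- p[3, 1]; cy <- p[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  tris <- list(super)
  ccs <- list(circum(super))
  for (ip in seq_len(n)) {
    p <- verts[ip, ]
    bad <- which(vapply(ccs, function(cc)
      (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3], TRUE))
    if (!length(bad))
      stop("Delaunay insertion failed (degenerate point configuration)")
    edges <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[[t]]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    keep_tri <- tris[-bad]
    keep_cc <- ccs[-bad]
    # boundary edges of the cavity appear exactly once
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      tri <- c(boundary[e, ], ip)
      keep_tri <- c(keep_tri, list(tri))
      keep_cc <- c(keep_cc, list(circum(tri)))
    }
    tris <- keep_tri
    ccs <- keep_cc
  }
  E <- NULL
  for (tr in tris) {
    if (any(tr %in% super)) next
    E <- rbind(E, rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)])))
  }
  unique(E)
}

#' Generate a synthetic study geography
#'
#' Stands in for a real municipal geography so every simulation scenario
#' runs without a download: an irregular point cloud of centroids (jittered
#' grid on the unit square), contiguity adjacency from the Delaunay
#' triangulation of the centroids (the graph of neighbouring Voronoi
#' cells), log-normal populations (median 20 000, sd of log 1 — spanning
#' several orders of magnitude like municipal populations), and
#' gravity-model movement flows between all pairs.
#'
#' @param n number of areas (>= 10).
#' @param seed integer seed.
#' @param gamma,kappa gravity-model parameters passed to [gravity_flows()].
#' @return list with `geography` ([geography()]) and `flows`
#'   ([gravity_flows()] output).
#' @export
synthetic_geography <- function(n, seed, gamma = 2, kappa = 1) {
  if (n < 10L) stop("need at least 10 areas")
  set.seed(seed)
  g <- ceiling(sqrt(n))
  cells <- expand.grid(ix = seq_len(g), iy = seq_len(g))
  cells <- cells[sample.int(nrow(cells), n), ]
  pts <- cbind((cells$ix - stats::runif(n, 0.15, 0.85)) / g,
               (cells$iy - stats::runif(n, 0.15, 0.85)) / g)
  pops <- stats::rlnorm(n, meanlog = log(2e4), sdlog = 1)
  ed <- delaunay_edges(pts)
  W <- matrix(0, n, n)
  W[ed] <- 1
  W <- pmax(W, t(W))
  geog <- geography(area_ids = sprintf("A%03d", seq_len(n)), centroids = pts,
                    populations = pops, adjacency = W)
  flows <- gravity_flows(pops, pts, gamma = gamma, kappa = kappa)
  list(geography = geog, flows = flows)
}

#' Write a simulated dataset as CSV
#'
#' Columns: `area_id`, `count`, `population`, `true_S` and one
#' `true_smooth_*` column per smooth component.
#'
#' @param sim `sm_simulated`.
#' @param path output CSV path.
#' @export
write_simulated_csv <- function(sim, path) {
  d <- data.frame(area_id = sim$geography$area_ids, count = sim$y,
                  population = sim$geography$populations,
                  true_S = sim$true_S)
  for (nm in names(sim$true_smooths))
    d[[paste0("true_smooth_", nm)]] <- sim$true_smooths[[nm]]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
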