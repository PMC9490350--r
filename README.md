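# splinemap

Bayesian disease mapping in which the spatially structured random effects
are **penalized thin-plate spline surfaces over connectivity coordinates**
instead of a fixed neighbourhood (CAR) structure. Connectivity coordinates
can be scaled geographic centroids (distance-based connectivity) or a 2-D
classical-MDS embedding of *any* symmetric connectivity measure — for
example gravity-model human-movement flows. Several surfaces with
different connectivity assumptions can enter one model, and their relative
contributions are quantified from posterior samples.

Intended users: spatial epidemiologists and biostatisticians fitting
area-level count (or binary) models who want the spatial structure learned
from the data, want to compare competing connectivity hypotheses
(distance vs movement), or want a like-for-like BYM2 comparator fitted by
the same MCMC machinery.

## The model

For counts `y_i` in `n` areas with exposure `ξ_i = population_i / 1e5`:

    y_i ~ p(E(y_i), ψ)                       p ∈ {Poisson, NB, Binomial}
    log E(y_i) = log ξ_i + α + u_1i + u_2i + v_i

Each `u_k` is a thin-plate regression spline surface
`f(x,z) = Σ_j β_j b_j(x,z)` over a 2-D connectivity coordinate system,
with the Bayesian smoothing prior `β ~ N(0, (λ0·P0 + λ1·P1)^-1)`
(`P1` = curvature penalty, `P0` = null-space penalty making the prior
proper); `v_i ~ N(0, σ_v²)` is iid heterogeneity. The comparator is the
BYM2 model `S = (√φ·u* + √(1−φ)·v*)/√τ` with a scaled intrinsic-CAR
`u*` on the contiguity graph. Posterior sampling is an own-written
HMC-within-Gibbs sampler (diagonal-mass/step-size warmup adaptation,
conjugate Gibbs for the smoothing precisions, interweaved rescaling moves
for the variance funnel). The relative contribution of each term is the
per-draw ratio `var(u_k) / var(u_1 + u_2 + v)` across areas, summarized
over draws; model comparison uses WAIC and MAE.

## Worked example

Simulate counts with a known 80/20 mixture of a distance-based smooth
field and unstructured noise on a 150-area synthetic geography, then
recover the decomposition:

```r
library(splinemap)

syn    <- synthetic_geography(150, seed = 11)      # centroids, adjacency, populations, gravity flows
coords <- scale_coordinates(syn$geography$centroids, "distance")
sim    <- single_source(syn$geography, coords, phi = 0.8, seed = 101)

basis <- build_tprs_basis(coords, K = 30, label = "distance")
spec  <- model_spec("poisson", offset = sim$offset,
                    smooth_terms = list(distance = basis))
post  <- run_mcmc(spec, sim$y, chains = 4, iterations = 2000,
                  burnin = 1000, seed = 1)

variance_proportion(post)
#> Random-term variance decomposition (posterior mean [95% CI]):
#>   distance     0.872 [0.373, 1.017]
#>   iid          0.128 [0.004, 0.598]
waic(post); mae(post); rhat(post)
#> WAIC: 213.07   MAE: 0.382   Rhat(alpha): 1.005
```

The distance surface is credited with ~87% of the random-term variance —
close to the structured share implied by `phi = 0.8` (0.94, since the
simulator mixes a unit-variance smooth field and unit-variance noise with
linear weights). The wide interval is honest: 150 sparse-count areas carry
limited information about a variance ratio.

Movement-based coordinates come from flows:

```r
cm <- movement_coordinates(syn$flows)      # MDS embedding of gravity flows
basis_m <- build_tprs_basis(cm, K = 30, label = "movement")
# add to smooth_terms for a two-source model, or fit comparator = "bym2"
```

## Command line

Reproducible runs are driven by YAML configs through five verbs:

```sh
exec/splinemap simulate config.yaml   # scenario grids (11 single- / 10 two-source datasets)
exec/splinemap fit      config.yaml   # MCMC fit; posterior CSV, decomposition JSON, report.json
exec/splinemap compare  config.yaml   # aggregate reports into a comparison table
exec/splinemap decompose config.yaml  # fit, keeping only the decomposition outputs
exec/splinemap mds      config.yaml   # standalone flow-matrix embedding
```

Every run directory contains a config echo, and each report embeds the
config md5 and seed. `fit` exits non-zero when R-hat > 1.1 on key
parameters.

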