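# locfuse — Bayesian grouping of SMLM localizations into emitters

Single-molecule localization microscopy (DNA-PAINT, dSTORM) produces lists of
*localizations*: noisy position estimates of individual blinking/binding
events, each with a reported precision. One *emitter* — the tagged molecule
or docking strand — typically generates many such events over an acquisition.
`locfuse` infers how many emitters generated a localization list, where they
are, and how many events each produced, by sampling the joint posterior

    pi(K, Z, mu, a, lambda) ∝ P(N | K, lambda) · K^(-N)
        · Π_i N(x_i; mu_{Z_i} + a_{Z_i} t_i, sigma_i²) · A^(-K)
        · Π_k N(a_k; 0, s_a²) · p(lambda)

with Reversible-Jump MCMC over the emitter count `K`, emitter positions
`mu_k` and optional linear drifts `a_k`, the allocation `Z` of localizations
to emitters, and the mean localizations-per-emitter `lambda` (learned
hierarchically or fixed from a control). Grouping the `n` events of an
emitter improves its position estimate roughly as `sigma/sqrt(n)`, so with
tens of events per emitter the returned coordinates reach nanometre and
sub-nanometre precision. The package also provides the surrounding
workflow: intensity and neighbor-count (NND) outlier filters, subregion
tiling and stitching, posterior and most-probable-model (MAPN) images and
coordinate tables, DNA-PAINT and dSTORM (three-state Gillespie) simulators
with ground truth, Hungarian-matched Jaccard/RMSE evaluation, spatial
statistics (nearest-neighbor distributions, Hopkins' statistic), and
Monte-Carlo rigid alignment of recovered structures for particle averaging.

It is intended for microscopists and image analysts who already have
localization tables (CSV/TSV with `x, y, sigma_x, sigma_y, frame, photons`)
from any fitting software, and for methods developers who need a tested
reference implementation of localization grouping with exact small-problem
oracles.

## Worked example

Simulate a dense DNA-PAINT field and group it:

```r
library(locfuse)
set.seed(4)
scene <- sim_density_field(17000, area = c(0, 100, 0, 100),
                           lambda = 50, n_frames = 1000)  # 170 emitters
sim <- simulate_blinks(scene)

fit <- locfuse(sim$set, n_samples = 3000, subregion_size = 20,
               extent = c(0, 100, 0, 100), seed = 11)
print(fit)
#> Bayesian grouping of localizations
#>   8584 localizations -> 193 emitters (25 subregions)
#>   median precision: input 3.38 nm -> grouped 0.79 nm
#>   localizations per emitter (learned mean): 43.8

mt <- match_emitters(scene$positions, fit$mapn)
jaccard(mt); rmse(mt, method = "mean")
#> [1] 0.824
#> [1] 0.98
```

8,584 localizations with a median 3.4 nm precision are grouped into 193
emitter estimates (170 simulated) with a median grouped precision of
0.8 nm; Hungarian matching against the ground truth gives a Jaccard index
of 0.82 at ~1 nm mean position error — the operating point of the method at
17,000 emitters/µm² (mean nearest-neighbor spacing 3.8 nm). The fitted object has
the usual modelling surface: `coef()` (emitter coordinates and precisions),
`residuals()` (localization-to-emitter distances), `plot()` (posterior image
with MAPN overlay), `simulate()` (new localization sets from the fitted
emitters), and `summary()`.

Lower-level entry points: `run_chain()` (one subregion, full chain access),
`mapn_extract()` / `posterior_image()` (chain summaries), `pipeline_run()`
(filtering + fitting + file outputs from a config list or YAML), and a thin
command-line front end in `inst/cli/locfuse` with `simulate`, `filter`,
`run`, `metrics` and `align` subcommands.

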