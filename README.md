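# simbaref

Simultaneous hierarchical Bayesian quantification and analysis of PET
time-activity curves (TACs) with reference-tissue models.

## The problem

Conventional non-invasive PET quantification is a two-stage process: fit
the simplified reference tissue model (SRTM) to each regional TAC by
nonlinear least squares (NLS), then carry the per-TAC binding-potential
estimates into a second statistical model. Each TAC is fitted alone, so
small or low-binding regions produce noisy, unstable estimates, and the
second stage never sees the measurement error of the first.

`simbaref` implements the SiMBA (simultaneous multifactor Bayesian
analysis) approach for reference-tissue models: every TAC of every
measurement of every subject is fitted in one hierarchical multivariate
model, so regional and between-subject similarity regularises each TAC's
parameters and the scientific contrasts (group differences, treatment
effects, age associations) are estimated jointly with quantification.

## The model

For each log-scale pharmacokinetic parameter
*i* ∈ {log R₁, log k₂′, log BP_ND} of subject *j* and region *k*:

    θ_ijk = α_i + X_ijᵀ β_i + τ_ij + υ_ik + φ_ijk

with multivariate-normal partially pooled deviations per subject (τ),
region (υ) and TAC (φ), and data model

    C_T(t_h) ~ Normal(μ_h, σ_h²),   μ_h = SRTM(θ; C_R),
    log σ_h = κ + covariates + smooth(t_h) + deviations,

where the SRTM prediction

    C_T(t) = R₁ C_R(t) + (k₂ − R₁ k₂ₐ) [C_R ⊗ exp(−k₂ₐ t)](t)

is fully analytic because the reference curve C_R is represented by a
nine-parameter Feng-1TC model (a delayed ramp-plus-tri-exponential input
convolved with a one-tissue impulse response) fitted once per measurement
by bounded multi-start least squares. The full reference tissue model
(FRTM, adds k₄) is provided as a forward model. Posterior sampling uses a
No-U-Turn sampler driven by exact gradients of a compiled (TMB) objective,
with a dense curvature metric and interleaved conditional updates of the
variance hyperparameters. The measurement-error model priors and effect
priors follow the published specification (see the methods vignette).

The package also ships the complete evaluation machinery: a realistic
study simulator with a noisy reference-curve library and known truth, the
conventional NLS + linear-mixed-effects comparison arm, and accuracy /
power / false-positive-rate / ICC(3,k) utilities.

## Worked example

Simulate a small two-group pre/post study (healthy volunteers on placebo,
patients on active treatment; patients average 0.08 lower log BP_ND and
treatment adds +0.04) and fit it both ways:

```r
library(simbaref)

lib   <- build_reference_library(n = 20, frames = short_frame_schedule(),
                                 n_starts = 8, seed = 2)
study <- simulate_dataset(population_params(),
                          study_design(n_hv = 3, n_patient = 3), lib, seed = 5)
dat   <- as_simba_data(study)        # uses *estimated* reference parameters

fit <- simba_fit(dat, chains = 2, iter = 400, warmup = 150, seed = 1)
fit
#> <simba_posterior: 500 draws (2 chains x 250), 430 parameters>
#>   max split-Rhat: 1.049 (converged); divergent: 9

nls <- nls_study(dat, n_starts = 3)
```

Comparing posterior-mean BP_ND per TAC with the simulation truth, against
the per-TAC NLS estimates (`rmse_and_r()`), this study prints:

```
  region  rmse_simba  rmse_nls  reduction_pct
  ACC     0.0123      0.0219    44.0
  AMG     0.0202      0.0397    49.1
  DBS     0.0126      0.0513    75.5
  FC      0.0116      0.0142    18.8
  HIP     0.0144      0.0270    46.6
  INS     0.0145      0.0217    33.1
  OC      0.0231      0.0283    18.3
  THA     0.0072      0.0145    50.1
  VSTR    0.0283      0.0539    47.5
```

Hierarchical estimation reduces BP_ND error in every region, most strongly
in the small, low-binding dorsal brain stem (DBS) — the same pattern the
method shows at scale. The treatment-minus-placebo contrast and the
marginal patient-minus-control difference are read off the same posterior:

```r
contrast_estimate(fit, c("b_logBPND[session_post:active]" = 1))$mean
#> 0.063      # this dataset's realized true contrast was 0.056
marginal_group_difference(fit)$mean
#> -0.055     # true -0.08; n = 3 per group
```

## Layout

- `R/`, `src/` — package code; the joint posterior is `src/simbaref.cpp`.
- `vignettes/simbaref-methods.Rmd` — models, priors, numerics, design
  decisions and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
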