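---
title: "Hierarchical Bayesian quantification of reference-tissue PET: models, priors and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian quantification of reference-tissue PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-invasive PET quantification estimates receptor availability from regional
time-activity curves (TACs) relative to a reference region without specific
binding. Conventionally this is a two-stage process: fit the simplified
reference tissue model (SRTM) to each TAC by nonlinear least squares, then
analyse the resulting binding-potential estimates in a second statistical
model. `simbaref` instead fits every TAC of every measurement of every
subject in a single hierarchical multivariate Bayesian model (the SiMBA
approach), so that quantification and analysis share one error model and
regional and between-subject similarity regularises the per-TAC estimates.

## Forward models

**SRTM.** Each target TAC is modelled as
$$C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\,[C_R \otimes e^{-k_{2a} t}](t),$$
with $k_2 = R_1 k_2'$ and $k_{2a} = k_2 / (1 + BP_{ND})$. The full model
(FRTM) adds the dissociation rate $k_4$; its closed form uses the two
macro-rates of the two-tissue characteristic polynomial and collapses onto
the SRTM as $k_4 \to \infty$. FRTM forward prediction is provided and
tested, but the Bayesian sampler implements the SRTM only: in our hands (as
in most applications) the four-parameter model is not identifiable enough
at realistic noise for routine posterior sampling, and its prior structure
would be speculative.

**The reference curve.** All convolutions are analytic because the measured
reference TAC is replaced by a nine-parameter "Feng-1TC" representation: a
delayed ramp-plus-tri-exponential input convolved with a one-tissue impulse
response $g e^{-w t}$. The parameters have no biological meaning; they are
a device that makes $C_R \otimes e^{-\theta t}$ closed-form. Every term
reduces to kernels $F_k(a, b, u) = \int_0^u s^{k-1} e^{-a s} e^{-b (u - s)} ds$.

**Numerical choices for the kernels.** Near rate coincidence ($|a - b| u <
0.05$) the kernels are evaluated by the Maclaurin series of
$\phi_k(x) = \int_0^1 u^{k-1} e^{-x u} du$ (7 terms, relative truncation
error $< 10^{-13}$); elsewhere by difference forms arranged so that every
exponential decays (no overflow for either sign of $a - b$). The series
*is* the coincident-rate limit, so predictions are continuous across the
degeneracy rather than switching at a hard threshold. The triple-kernel
degeneracy $\theta \approx w$ uses explicit limit values inside a
$|w-\theta| u < 10^{-6}$ window. Model curves are evaluated at frame
midpoints by default; an exact analytic frame-average mode is available
(`mode = "frame_average"`), since closed-form antiderivatives exist.

**Reference fitting.** `fit_reference()` is bounded multi-start
Levenberg-Marquardt (default 20 uniform-random starts inside the bounds,
frame-duration weights). The three decay-rate boxes are disjoint so the
canonical ordering $l_1 \ge l_2 \ge l_3$ holds for every bounded fit. On
coarse frame schedules the nine-parameter surface has a broad shallow local
minimum; 40 starts resolved every case we generated. Visual inspection is
replaced by `qc_reference()`: a runs test on signed residuals (p < 0.01
flags), a 10% peak-underestimation flag, a cohort-relative RSS flag, and a
per-fit diagnostic plot.

## The hierarchical model

For each log-scale PK parameter $i \in \{\log R_1, \log k_2', \log BP_{ND}\}$,
$$\theta_{i,j,k} = \alpha_i + X^T_{i,j}\beta_i + \tau_{i,j} + \upsilon_{i,k} + \phi_{i,j,k},$$
with subject ($\tau$), region ($\upsilon$) and TAC ($\phi$, measurement
$\times$ region) deviations. Data: $C_T(t_h) \sim N(\mu_h, \sigma_h^2)$ with
$\mu$ from the analytic SRTM and $\log \sigma_h$ a linear model on the
centred natural logs of frame duration, region volume and injected dose, a
thin-plate-spline smooth over frame time (basis dimension 8, built with
`mgcv`), and partially pooled deviations per PET measurement and per region.
"Per measurement" (rather than per person) is deliberate: the factors that
move the error level — dose, scanner state — attach to a session.

Covariates: region dummies for $\log R_1$ and $\log BP_{ND}$ (sum-to-zero
coding by default, so $\alpha$ is the cross-region mean); age in centred
decades for $\log k_2'$ and $\log BP_{ND}$; a diagnosis indicator, age
$\times$ diagnosis, session and session $\times$ active-arm (the
treatment-minus-placebo difference-in-difference) on $\log BP_{ND}$; centre
and centre $\times$ region terms on all three parameters when a dataset
spans centres. Regional $\log k_2'$ deviations are partially pooled
(half-normal SD hyperprior, scale 0.1) while regional $R_1$/$BP_{ND}$
differences are unpooled fixed dummies — regional binding is structured by
anatomy, not exchangeable. Partially pooled region $\times$ age slopes on
$\log BP_{ND}$ capture regional heterogeneity of the age association.

**Priors** (all configurable; `default_priors()`): normal(μ₀, 0.25) on the
global intercepts, with tracer-neutral placeholder centres (R₁ ≈ 0.85,
k₂′ ≈ 0.10 min⁻¹, BP_ND ≈ 1.0) that should be set per radiotracer;
half-normal scales 0.3/0.1/0.3 on subject-level SDs of
logR₁/logk₂′/logBP_ND, 0.1 on the pooled regional k₂′ SD; normal(0, 0.3)
on region dummies; normal(0, 0.1) on age, centre and centre × region
effects; normal(0, 0.05) on diagnosis and treatment effects; LKJ(2) on
correlation matrices.

**TAC-level deviations.** The TAC deviation SD is stated as 0.025 for all
parameters; we read this as a *direct* normal SD (the deviations are tiny
nuisance wobbles), so $\phi \sim \mathrm{MVN}(0, D R D)$ with $D = 0.025 I$
fixed and only the correlation $R$ estimated. The alternative hyperprior
reading leaves the $\log k_2'$ TAC-level scale unidentified: its likelihood
is flat over a long left tail and no sampler we tried mixed it (split-Rhat
1.7–4 at desk-scale chain lengths). By default $R$ couples only
$\log R_1$ and $\log BP_{ND}$ — the margins the data identify per TAC —
with the $\log k_2'$ TAC deviation independent
(`tac_correlation = "r1_bpnd"`); the full 3×3 structure is available
(`"full"`) but its $BP_{ND}$–$k_2'$ partial correlation is a
near-unidentified collective mode that needs chain lengths far beyond a
desk budget. Subject-level correlations are always the full 3×3.

## Posterior computation

The joint posterior is compiled with TMB (C++ automatic differentiation);
the parameter-independent halves of every convolution kernel are
precomputed on the observation grid, leaving roughly one exponential per
observation on the AD tape. Sampling is a package-native multinomial
No-U-Turn sampler with dual-averaging step-size adaptation.

Three numerical choices matter at realistic PET noise:

* **Parameterisation.** The likelihood dominates most deviation blocks, so
  they are *centred* (non-centred forms produced the classic data-rich
  pathology: step sizes ~0.015, saturated trees, divergences). The one
  weakly identified margin — the TAC-level $\log k_2'$ deviation — is
  non-centred through its conditional given the other margins.
* **Metric.** The hierarchical mean decomposition makes
  $\alpha$/dummies/$\tau$/$\phi$ strongly linearly dependent, which no
  diagonal metric can remove. Chains use a fixed *dense* metric: the full
  Hessian of the negative log posterior at a data-driven start (quick
  per-TAC NLS estimates decomposed into the model components), with the
  spectrum floored at the prior curvature scale, refreshed once mid-warmup
  at the current state, and a reasonable-step-size search after every
  metric change.
* **Interleaved conditional updates.** Variance and correlation
  hyperparameters ride long shallow ridges that HMC trajectories traverse
  slowly. Between NUTS iterations the sampler performs exact 1-D
  slice-Gibbs updates of every deviation-SD and correlation parameter
  (their conditionals given the centred deviations are closed form) plus
  Haar-corrected scale-group moves that jointly rescale a block and its SD
  through the full posterior.

Convergence is reported as split-Rhat for every scalar parameter with a
hard gate at 1.05 (a warning flags any fit beyond it), plus effective
sample sizes, divergence counts and tree statistics. Defaults are 3 chains
of 1000 iterations (warmup half), as in the reference implementation;
the package's own tests use 300-iteration chains on reduced designs.

## The simulator

`simulate_dataset()` generates studies with known truth following the
reference design: equal healthy-volunteer and patient groups, patients
0.08 lower in mean $\log BP_{ND}$, pre/post sessions where active treatment
adds +0.04 to $\log BP_{ND}$ and placebo adds 0 (session differences then
arise only through TAC-level variation). Reference curves come from a
library (default 500 entries) built by resampling base Feng-1TC shapes,
adding frame-level noise by the five-step construction (per-frame
$\log\sigma$ profile + mean level + PET-to-PET deviation, summed in
$\log\sigma$, then Gaussian noise per time point), and refitting each noisy
curve — every entry carries *true* parameters/curve and *measured*
curve/*estimated* parameters, and the generator consumes only the former
while model fitting consumes only the latter.

Generator defaults are plausible stand-ins chosen once (the study-specific
posterior means they emulate are not public): nine regions named
ACC/AMG/DBS/FC/HIP/INS/OC/THA/VSTR with mean $BP_{ND}$ 0.35–1.9 (DBS
medium-low, OC high), subject-level log-scale SDs (0.06, 0.08, 0.20) with
$R_1$–$BP_{ND}$ correlation 0.5, TAC-level SDs 0.025, ages uniform 22–70
with a −0.04/decade $BP_{ND}$ age effect, doses ~N(350, 25) MBq, and a
σ-model with counting-statistics-like coefficients (−0.5 on log frame
duration and log volume, −0.3 on log dose), a smooth early-dip/late-rise
profile over scan time, and PET-to-PET $\log\sigma$ SD 0.2. At these
settings the reference region (60 mL) has ~1–2% of peak noise and the
smallest region (DBS, 1.8 mL) ~5–8%, which is what drives the large
accuracy gains of partial pooling there. What the simulator does *not*
emulate: motion, scatter/attenuation artefacts, partial-volume effects,
violations of the reference-region assumption, or non-Gaussian frame
noise — passing tests show statistical behaviour under the model's own
assumptions, not robustness to these.

Default frame schedules: a 38-frame/93-minute acquisition
(`default_frame_schedule()`) and a coarser 20-frame/60-minute schedule
(`short_frame_schedule()`) used throughout the package's tests and
acceptance script to keep runtimes at desk scale.

## Identifiability of the clinical effects

With the regularising normal(0, 0.05) prior on clinical effects, the
*fixed* diagnosis coefficient is necessarily shrunk whenever the
between-subject standard error exceeds the prior scale (which it does at
any desk-scale n); the raw coefficient cannot recover a −0.08 group
difference, and no estimator could unconfound it from the group difference
in subject deviations — only their sum is identified. The estimand the
simulation injects is therefore the *marginal* group difference, computed
per draw as the fixed effect plus the difference in mean subject
deviations (`marginal_group_difference()`); it is unbiased for −0.08. The
within-subject treatment contrast has no such confound and its posterior
centres on +0.04 across replicates.

## Evaluation utilities

`rmse_and_r()` gives per-region RMSE and Pearson r against truth with
percentage RMSE reductions versus a baseline method; `icc3k()` is the
two-way mixed, consistency, average-measures intraclass correlation with
the F-based interval; `se_reduction()` summarises paired standard-error
reductions. The conventional arm is per-TAC bounded multi-start NLS with
numerical convolution of the *measured* (interpolated) reference TAC —
deliberately independent of the Feng-1TC machinery — followed by a linear
mixed model of $\log BP_{ND}$ with random intercepts for subject and
region (`lmerTest`, Satterthwaite p-values; singular fits fall back to a
subject-only structure). Rejection rates over replicates are estimated
empirically (exact binomial CI) or from a smooth density over the
replicate statistics: the tail mass of a Gaussian-kernel density beyond
the two-sided critical value, with a bootstrap CI.

## Problem sizes used by the shipped tests and acceptance script

The reference replicate campaigns (hundreds of two-stage fits, tens of
multi-day Bayesian fits) are cluster-scale. The package's own checks use:
a 25-entry reference library and a 6 + 6-subject, pre/post, five-region
study (3 chains × 300 iterations) for accuracy comparisons; 20 null and 10
effect replicates of a 3 + 3-subject, two-session, three-region design
(single 200-iteration chains) for calibration and recovery; and a
500-entry library with a 6 + 6-subject pre/post five-region study in the
acceptance script. These sizes preserve the direction-of-effect properties
(hierarchical estimation beats per-TAC NLS in every region; nominal false-
positive rate; unbiased contrast recovery) while magnitudes of the
headline percentages depend on the exact generative settings.

## Known limitations

* The FRTM is not sampled, only predicted.
* Reference-curve parameters enter the Bayesian model as fixed known
  quantities; their (small) uncertainty is not propagated.
* The full TAC-level correlation structure is impractical to sample at
  desk scale (see above).
* Posterior-predictive machinery is limited to what the evaluation
  utilities need; no PSIS-LOO effective-parameter estimation or
  power-scaling prior diagnostics are included.
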