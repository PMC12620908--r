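# Shared expensive fixtures for the acceptance suite, built once per run.
# Sizes are desk-scale reductions of the reference study design (the methods
# vignette documents them as package choices): the accuracy fixture uses
# 6 + 6 subjects, one session and five regions spanning the binding range;
# replicate runs use 3 + 3 subjects, two sessions and three regions.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

acc_library <- function() {
  .memo("library", function() {
    build_reference_library(n = 25, frames = short_frame_schedule(),
                            n_starts = 10, seed = 401)
  })
}

acc_main <- function() {
  .memo("main", function() {
    lib <- acc_library()
    pop <- subset_regions(population_params(),
                          c("FC", "OC", "HIP", "DBS", "THA"))
    des <- study_design(n_hv = 6, n_patient = 6)
    study <- simulate_dataset(pop, des, lib, seed = 402)
    dat <- as_simba_data(study)
    fit <- suppressWarnings(
      simba_fit(dat, chains = 3, iter = 300, warmup = 75, seed = 403,
                max_treedepth = 8, target_accept = 0.9))
    nls <- nls_study(dat, n_starts = 3, seed = 404)
    list(study = study, dat = dat, fit = fit, nls = nls,
         truth = sim_truth(study))
  })
}

# one reduced-scale pre/post study + single-chain SiMBA fit; returns the
# treatment-minus-placebo contrast summary and the marginal group difference
simba_replicate <- function(seed, treatment_effect = 0.04) {
  lib <- acc_library()
  pop <- subset_regions(
    population_params(treatment_effect_logbpnd = treatment_effect),
    c("FC", "HIP", "DBS"))
  des <- study_design(n_hv = 3, n_patient = 3)
  study <- simulate_dataset(pop, des, lib, seed = 10000 + seed)
  dat <- as_simba_data(study)
  fit <- suppressWarnings(
    simba_fit(dat, chains = 1, iter = 200, warmup = 80, seed = seed,
              max_treedepth = 6, target_accept = 0.85))
  ce <- contrast_estimate(fit, c("b_logBPND[session_post:active]" = 1))
  mg <- marginal_group_difference(fit)
  tibble::tibble(seed = seed,
                 estimate = ce$mean, se = ce$sd, p = ce$tail_prob,
                 lo95 = ce$ci95[1], hi95 = ce$ci95[2],
                 group_diff = mg$mean)
}

lme_replicate <- function(seed, treatment_effect = 0) {
  lib <- acc_library()
  pop <- subset_regions(
    population_params(treatment_effect_logbpnd = treatment_effect),
    c("FC", "HIP", "DBS"))
  des <- study_design(n_hv = 3, n_patient = 3)
  study <- simulate_dataset(pop, des, lib, seed = 20000 + seed)
  dat <- as_simba_data(study)
  est <- nls_study(dat, n_starts = 1, seed = seed)
  res <- fit_lme_contrast(est)
  tibble::tibble(seed = seed, estimate = res$estimate, se = res$se, p = res$p)
}
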