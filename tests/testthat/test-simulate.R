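# small shared fixtures: a coarse schedule and a small reference library
local_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) {
      lib <<- build_reference_library(n = 15, frames = short_frame_schedule(),
                                      n_starts = 6, seed = 11)
    }
    lib
  }
})

test_that("frame noise follows the five-step log-additive construction", {
  fs <- short_frame_schedule()
  truth <- ref_curve(fs$frame_mid, example_ref_params())
  comp <- list(logsigma_mean = log(0.1), logsigma_frame = rep(0, nrow(fs)),
               sd_meas = 0.2)
  # sd -> 0 limit: output equals input
  comp0 <- list(logsigma_mean = -30, logsigma_frame = rep(0, nrow(fs)),
                sd_meas = 0)
  nz0 <- simulate_frame_noise(truth, comp0, seed = 1)
  expect_equal(nz0$curve, truth, tolerance = 1e-10)
  # +ln 2 measurement deviation doubles every frame sigma
  nzA <- simulate_frame_noise(truth, c(comp, meas_dev = 0), seed = 2)
  nzB <- simulate_frame_noise(truth, c(comp, meas_dev = log(2)), seed = 2)
  expect_equal(nzB$sigma, 2 * nzA$sigma)
  # Monte-Carlo moment check on one frame
  draws <- vapply(1:4000, function(i) {
    simulate_frame_noise(truth[5], c(comp, meas_dev = 0), seed = 10000 + i)$curve
  }, numeric(1))
  expect_equal(sd(draws), 0.1, tolerance = 0.04)
  # determinism
  expect_identical(simulate_frame_noise(truth, comp, seed = 9),
                   simulate_frame_noise(truth, comp, seed = 9))
})

test_that("reference library entries carry the four elements with faithful noise", {
  lib <- local_lib()
  expect_length(lib$entries, 15)
  e <- lib$entries[[1]]
  expect_s3_class(e$true_params, "ref_curve_params")
  expect_s3_class(e$estimated_params, "ref_curve_params")
  expect_length(e$true_curve, nrow(lib$frames))
  expect_length(e$measured_curve, nrow(lib$frames))
  # default library size is the full 500
  expect_equal(eval(formals(build_reference_library)$n), 500)
  # noise-free library: measured == true and refit recovers the curve
  # coarse schedules need a denser multi-start sweep to escape a broad
  # local minimum of the nine-parameter fit
  lib0 <- build_reference_library(n = 3, frames = short_frame_schedule(),
                                  noise_scale = 0, n_starts = 40, seed = 2)
  for (e0 in lib0$entries) {
    expect_equal(e0$measured_curve, e0$true_curve, tolerance = 1e-9)
    est_curve <- ref_curve(lib0$frames$frame_mid, e0$estimated_params)
    expect_lt(max(abs(est_curve - e0$true_curve)) / max(e0$true_curve), 0.005)
  }
  # empirical residual SD across the library tracks the generative sigma
  z <- vapply(lib$entries, function(e) {
    (e$measured_curve - e$true_curve) / e$sigma
  }, numeric(nrow(lib$frames)))
  expect_equal(sd(as.vector(z)), 1, tolerance = 0.10)
})

test_that("subject parameter simulation applies effects exactly and reproducibly", {
  pop <- population_params()
  # zero covariances, zero effects: parameters equal exp(alpha + region dev)
  pop0 <- pop
  pop0$Sigma_subject[] <- 0
  pop0$Sigma_tac[] <- 0
  pop0$age_effect[] <- 0
  pop0$group_effect_logbpnd <- 0
  pop0$treatment_effect_logbpnd <- 0
  class(pop0) <- "population_params"
  tr <- simulate_subject_params(pop0, list(group = "HV", arm = "placebo", age = 46),
                                sessions = "baseline", seed = 4)
  expect_equal(tr$bpnd,
               unname(exp(pop$alpha["logBPND"] + pop$region_dev[tr$region, "logBPND"])),
               tolerance = 1e-12)
  # patient vs HV at identical draws: logBPND differs by exactly -0.08
  hv <- simulate_subject_params(pop, list(group = "HV", arm = "placebo", age = 50),
                                sessions = "pre", seed = 7)
  pat <- simulate_subject_params(pop, list(group = "MDD", arm = "placebo", age = 50),
                                 sessions = "pre", seed = 7)
  expect_equal(pat$logBPND - hv$logBPND, rep(-0.08, nrow(hv)))
  expect_equal(pat$logR1, hv$logR1)
  # active-arm post session: +0.04 on top of the same draws
  pre_post <- simulate_subject_params(pop0, list(group = "MDD", arm = "active", age = 50),
                                      sessions = c("pre", "post"), seed = 3)
  pop04 <- pop0
  pop04$treatment_effect_logbpnd <- 0.04
  class(pop04) <- "population_params"
  pre_post4 <- simulate_subject_params(pop04, list(group = "MDD", arm = "active", age = 50),
                                       sessions = c("pre", "post"), seed = 3)
  expect_equal(pre_post4$logBPND[pre_post4$session == "post"] -
                 pre_post$logBPND[pre_post$session == "post"], rep(0.04, 9))
  expect_equal(pre_post4$logBPND[pre_post4$session == "pre"],
               pre_post$logBPND[pre_post$session == "pre"])
})

test_that("subject-level draws recover the generative covariance", {
  pop <- population_params()
  draws <- simbaref:::.mvn_draw(20000, pop$Sigma_subject)
  emp <- cov(draws)
  expect_lt(norm(emp - pop$Sigma_subject, "F") / norm(pop$Sigma_subject, "F"),
            0.05)
})

test_that("effect conservation across many subjects", {
  pop <- population_params()
  logbp <- function(group, seeds) {
    vapply(seeds, function(s) {
      mean(simulate_subject_params(pop, list(group = group, arm = "placebo", age = 46),
                                   sessions = "pre", seed = s)$logBPND)
    }, numeric(1))
  }
  n <- 400
  d_hv <- logbp("HV", 1:n)
  d_pat <- logbp("MDD", n + 1:n)
  mc_se <- sqrt(var(d_hv) / n + var(d_pat) / n)
  expect_lt(abs(mean(d_pat) - mean(d_hv) + 0.08), 3 * mc_se)
})

test_that("simulated datasets have the right shape, determinism and audit split", {
  lib <- local_lib()
  des <- study_design(n_hv = 2, n_patient = 2)
  study <- simulate_dataset(population_params(), des, lib, seed = 21)
  # 4 subjects x 2 sessions x 9 regions
  expect_equal(nrow(study$meta), 8)
  expect_equal(nrow(study$truth), 8 * 9)
  dat <- as_simba_data(study)
  expect_equal(nrow(dplyr::distinct(dat$tacs, meas_id, region)), 72)
  # bit-identical regeneration from (design, seed)
  study2 <- simulate_dataset(population_params(), des, lib, seed = 21)
  expect_identical(study$truth, study2$truth)
  expect_identical(study$tac_rows, study2$tac_rows)
  # true-vs-estimated split
  expect_identical(attr(dat, "audit")$ref_source, "estimated")
  expect_identical(study$ref_source_simulation, "true_params")
  e <- study$library$entries[[study$meta$lib_idx[1]]]
  expect_false(identical(unlist(e$true_params), unlist(e$estimated_params)))
  expect_identical(unlist(dat$ref_params[[study$meta$meas_id[1]]]),
                   unlist(e$estimated_params))
  tru_dat <- as_simba_data(study, ref = "true")
  expect_identical(unlist(tru_dat$ref_params[[study$meta$meas_id[1]]]),
                   unlist(e$true_params))
  # placebo pre/post truths differ only through TAC-level variation (zero mean shift)
  tr <- sim_truth(study)
  plc <- tr[tr$arm == "placebo", ]
  diffs <- plc$logBPND[plc$session == "post"] - plc$logBPND[plc$session == "pre"]
  sd_tac <- sqrt(population_params()$Sigma_tac[3, 3])
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-12)
  expect_lt(sd(diffs), 3 * sd_tac * sqrt(2))
})

test_that("round-trip: zero-noise study is recovered by per-TAC NLS", {
  pop <- population_params()
  pop$Sigma_subject[] <- 0
  pop$Sigma_tac[] <- 0
  pop$sigma$kappa0 <- -30   # effectively noise-free target TACs
  pop$sigma$sd_meas <- 0
  pop$sigma$sd_region <- 0
  class(pop) <- "population_params"
  lib0 <- build_reference_library(n = 4, frames = short_frame_schedule(),
                                  pop = population_params(), noise_scale = 0,
                                  n_starts = 8, seed = 5)
  des <- study_design(n_hv = 1, n_patient = 0, sessions = "baseline")
  study <- simulate_dataset(pop, des, lib0, seed = 3)
  dat <- as_simba_data(study)
  est <- nls_study(dat, n_starts = 3, seed = 2)
  tr <- sim_truth(study)
  cmp <- dplyr::inner_join(est, tr, by = c("meas_id", "region"),
                           suffix = c("_est", "_true"))
  expect_lt(max(abs(cmp$R1_est - cmp$R1_true) / cmp$R1_true), 0.005)
  expect_lt(max(abs(cmp$bpnd_est - cmp$bpnd_true) / cmp$bpnd_true), 0.005)
})
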