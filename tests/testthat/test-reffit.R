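test_that("noise-free reference TACs are recovered to a fraction of a percent", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  truth <- ref_curve(fs$frame_mid, p)
  fit <- fit_reference(truth, fs, n_starts = 20, seed = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$fitted_curve - truth)) / max(truth), 0.005)
  expect_length(unlist(fit$params), 9)
})

test_that("multi-start fitting is deterministic and monotone in n_starts", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  truth <- ref_curve(fs$frame_mid, p)
  noisy <- truth + withr::with_seed(7, rnorm(length(truth), 0, 0.15))
  f1 <- fit_reference(noisy, fs, n_starts = 1, seed = 3)
  f20 <- fit_reference(noisy, fs, n_starts = 20, seed = 3)
  f20b <- fit_reference(noisy, fs, n_starts = 20, seed = 3)
  expect_identical(f20[c("params", "rss", "fitted_curve")],
                   f20b[c("params", "rss", "fitted_curve")])
  expect_lte(f20$rss, f1$rss)
})

test_that("fitted parameters respect the canonical rate ordering and bounds", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  noisy <- ref_curve(fs$frame_mid, p) +
    withr::with_seed(11, rnorm(nrow(fs), 0, 0.1))
  fit <- fit_reference(noisy, fs, n_starts = 10, seed = 5)
  pp <- fit$params
  expect_true(pp$l1 >= pp$l2 && pp$l2 >= pp$l3 && pp$l3 >= 0)
  b <- reference_fit_bounds(noisy)
  v <- unlist(pp)[names(b$lower)]
  expect_true(all(v >= b$lower - 1e-9 & v <= b$upper + 1e-9))
})

test_that("recovery at realistic noise: median curve error below 2% of peak", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  truth <- ref_curve(fs$frame_mid, p)
  pop <- population_params()
  lsf <- simbaref:::.sigma_frame_profile(fs, pop$sigma)
  lsm <- simbaref:::.sigma_level(pop$sigma, pop$reference_volume, pop$dose_mean)
  errs <- vapply(1:50, function(i) {
    nz <- simulate_frame_noise(truth, list(logsigma_mean = lsm,
                                           logsigma_frame = lsf,
                                           sd_meas = pop$sigma$sd_meas),
                               seed = 100 + i)
    f <- fit_reference(nz$curve, fs, n_starts = 10, seed = 5)
    sqrt(mean((f$fitted_curve - truth)^2)) / max(truth)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("runs test flags structured residuals and matches a combinatorial oracle", {
  # alternating signs: many runs, no flag
  alt <- rep(c(0.1, -0.1), 15)
  expect_gt(simbaref:::.runs_test_p(alt)$p, 0.5)
  # all negatives then all positives: 2 runs
  blocky <- c(rep(-0.1, 15), rep(0.1, 15))
  rt <- simbaref:::.runs_test_p(blocky)
  expect_equal(rt$runs, 2)
  # oracle: normal approximation of the runs distribution
  n1 <- 15; n2 <- 15; n <- 30
  mu <- 2 * n1 * n2 / n + 1
  s2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  expect_equal(rt$p, pnorm((2 - mu) / sqrt(s2)))
  expect_lt(rt$p, 0.01)
})

test_that("qc_reference raises the intended flags on constructed violations", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  truth <- ref_curve(fs$frame_mid, p)
  noisy <- truth + withr::with_seed(3, rnorm(nrow(fs), 0, 0.05))
  fit <- fit_reference(noisy, fs, n_starts = 10, seed = 2)
  clean <- qc_reference(fit, noisy)
  expect_length(clean$qc_flags, 0)
  # scaled-down fitted curve: peak underestimation + structured residuals
  broken <- fit
  broken$fitted_curve <- 0.8 * fit$fitted_curve
  flagged <- qc_reference(broken, noisy)
  expect_true("peak_underestimation" %in% flagged$qc_flags)
  # relative-RSS heuristic
  rssy <- qc_reference(fit, noisy, cohort_median_rss = fit$rss / 10)
  expect_true("high_rss" %in% rssy$qc_flags)
})

test_that("fit_reference validates its preconditions", {
  fs <- short_frame_schedule()
  tac <- ref_curve(fs$frame_mid, example_ref_params())
  expect_error(fit_reference(tac[1:5], fs), "match")
  expect_error(fit_reference(tac, fs, n_starts = 0), "n_starts")
  few <- frame_schedule(0:5, rep(1, 6))
  expect_error(fit_reference(tac[1:6], few), "10 frames")
  bad <- reference_fit_bounds(tac)
  bad$lower["w"] <- bad$upper["w"]
  expect_error(fit_reference(tac, fs, bounds = bad), "bounds")
})
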