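test_that("exp_conv_exp matches closed forms, quadrature, and rejects bad input", {
  expect_equal(exp_conv_exp(0, 0, 7), 7)
  expect_equal(exp_conv_exp(1, 1, 2), 2 * exp(-2))
  # quadrature oracle
  quad <- integrate(function(s) exp(-0.2 * s) * exp(-0.5 * (10 - s)), 0, 10,
                    rel.tol = 1e-12)$value
  expect_equal(exp_conv_exp(0.2, 0.5, 10), quad, tolerance = 1e-8)
  # symmetric in (a, b)
  expect_equal(exp_conv_exp(0.3, 0.07, 40), exp_conv_exp(0.07, 0.3, 40))
  expect_error(exp_conv_exp(-1, 0, 1), "non-negative")
  expect_error(exp_conv_exp(1, 1, -1), "non-negative")
})

test_that("convolution kernels are continuous across the rate degeneracy", {
  for (a in c(0.1, 0.3, 2)) {
    for (t in c(1, 30, 90)) {
      expect_lt(abs(exp_conv_exp(a, a + 1e-8, t) - exp_conv_exp(a, a, t)), 1e-6)
    }
  }
  # and across the series/exact switch itself
  a <- 0.3; t <- 50
  b_lo <- a + 0.05 / t * (1 - 1e-9)
  b_hi <- a + 0.05 / t * (1 + 1e-9)
  expect_equal(exp_conv_exp(a, b_lo, t), exp_conv_exp(a, b_hi, t),
               tolerance = 1e-10)
})

test_that("feng_input is zero before onset, continuous at onset, peak matches grid search", {
  p <- example_ref_params()
  expect_equal(feng_input(c(0, 0.2, 0.5), p), c(0, 0, 0))
  expect_lt(abs(feng_input(p$t0 + 1e-9, p)), 1e-6)
  tg <- seq(p$t0, p$t0 + 5, by = 1e-4)
  grid_peak <- tg[which.max(feng_input(tg, p))]
  expect_lt(abs(simbaref:::feng_input_peak(p) - grid_peak), 0.01)
})

test_that("ref_curve matches numerical convolution and handles trivial cases", {
  p <- example_ref_params()
  o <- oracle_curves(p, NULL)
  t_chk <- c(0.5, 1, 2, 5, 10, 30, 60, 90)
  idx <- grid_index(o$tg, t_chk)
  expect_lt(max(abs(ref_curve(t_chk, p) - o$cr[idx])) / max(o$cr), 1e-3)
  p0 <- ref_curve_params(0.5, 60, 3, 1, 4, 0.5, 0.02, 0, 0.12)  # g = 0
  expect_equal(ref_curve(c(1, 10, 50), p0), c(0, 0, 0))
  expect_equal(ref_curve(c(0, 0.3), p), c(0, 0))                # t <= t0
})

test_that("curves scale linearly in the input amplitudes", {
  p <- example_ref_params()
  p2 <- ref_curve_params(0.5, 180, 9, 3, 4, 0.5, 0.02, 0.4, 0.12)  # x3
  tt <- c(1, 5, 20, 60)
  expect_equal(ref_curve(tt, p2), 3 * ref_curve(tt, p))
  fs <- short_frame_schedule()
  kp <- kinetic_params(0.9, 0.12, 1.5)
  expect_equal(srtm_predict(fs, kp, p2), 3 * srtm_predict(fs, kp, p))
})

test_that("SRTM/FRTM/reference predictions agree with the numerical oracle over random draws", {
  set.seed(421)
  fs <- default_frame_schedule()
  n_draws <- 40   # the full 100-draw sweep runs in the acceptance suite
  worst <- 0
  for (i in seq_len(n_draws)) {
    p <- random_ref_params()
    frtm <- i %% 3 == 0
    kp <- if (frtm) random_kinetic_params(k4 = runif(1, 0.02, 0.4)) else
      random_kinetic_params()
    o <- oracle_curves(p, kp, dt = 0.001, frtm = frtm)
    idx <- grid_index(o$tg, fs$frame_mid)
    pred <- if (frtm) frtm_predict(fs, kp, p) else srtm_predict(fs, kp, p)
    err <- max(abs(pred - o$ct[idx])) / max(o$ct)
    worst <- max(worst, err)
    cr_err <- max(abs(ref_curve(fs$frame_mid, p) - o$cr[idx])) / max(o$cr)
    worst <- max(worst, cr_err)
  }
  expect_lt(worst, 1e-3)
})

test_that("identity limit: BPND = 0 and R1 = 1 reproduce the reference curve", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  cr <- ref_curve(fs$frame_mid, p)
  kp <- kinetic_params(1, 0.12, 0)
  expect_identical(max(abs(srtm_predict(fs, kp, p) - cr)), 0)
  kpf <- kinetic_params(1, 0.12, 1e-14, k4 = 0.1)
  expect_lt(max(abs(frtm_predict(fs, kpf, p) - cr)), 1e-10)
})

test_that("FRTM approaches SRTM in the rapid-equilibration limit", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  kp <- kinetic_params(0.9, 0.12, 1.5)
  kpf <- kinetic_params(0.9, 0.12, 1.5, k4 = 100)
  srtm <- srtm_predict(fs, kp, p)
  expect_lt(max(abs(frtm_predict(fs, kpf, p) - srtm)) / max(srtm), 0.005)
})

test_that("frame-average mode matches dense averaging of the oracle curve", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  kp <- kinetic_params(0.9, 0.12, 1.5)
  o <- oracle_curves(p, kp, dt = 0.001)
  fa <- srtm_predict(fs, kp, p, mode = "frame_average")
  dense <- vapply(seq_len(nrow(fs)), function(i) {
    s <- fs$frame_start[i]; e <- s + fs$frame_duration[i]
    mean(o$ct[o$tg >= s & o$tg < e])
  }, numeric(1))
  expect_lt(max(abs(fa - dense)) / max(o$ct), 1e-3)
})

test_that("kinetic_params derives k2, k2a, k3 consistently and validates input", {
  kp <- kinetic_params(0.9, 0.12, 1.5, k4 = 0.1)
  expect_equal(kp$k2, 0.9 * 0.12)
  expect_equal(kp$k2a, kp$k2 / 2.5)
  expect_lte(kp$k2a, kp$k2)
  expect_equal(kp$k3 / kp$k4, kp$bpnd)
  expect_error(kinetic_params(-1, 0.1, 1), "R1")
  expect_error(kinetic_params(1, 0.1, 1, k4 = 0), "k4")
  expect_error(srtm_predict(short_frame_schedule(), kp, example_ref_params()),
               "k4")
})

test_that("frame schedules validate timing invariants", {
  expect_error(frame_schedule(c(0, 1), c(2, 1)), "overlap")
  expect_error(frame_schedule(c(1, 0), c(0.5, 0.5)), "non-decreasing")
  expect_error(frame_schedule(0, 0), "> 0")
  fs <- default_frame_schedule()
  expect_equal(nrow(fs), 38)
  expect_equal(max(fs$frame_start + fs$frame_duration), 93)
  expect_equal(fs$frame_mid, fs$frame_start + fs$frame_duration / 2)
})
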