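test_that("conventional NLS recovers noise-free SRTM parameters", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  ref_tac <- ref_curve(fs$frame_mid, p)
  kp <- kinetic_params(0.9, 0.12, 1.5)
  tac <- srtm_predict(fs, kp, p)
  est <- fit_srtm_nls(tac, ref_tac, fs, n_starts = 4, seed = 2)
  expect_true(est$converged)
  expect_lt(abs(est$R1 - 0.9) / 0.9, 0.005)
  expect_lt(abs(est$bpnd - 1.5) / 1.5, 0.005)
})

test_that("bpnd lower bound: a non-binding TAC fits to R1 times the reference", {
  p <- example_ref_params()
  fs <- default_frame_schedule()
  ref_tac <- ref_curve(fs$frame_mid, p)
  kp <- kinetic_params(0.85, 0.12, 0)
  tac <- srtm_predict(fs, kp, p)
  est <- fit_srtm_nls(tac, ref_tac, fs, n_starts = 4, seed = 2)
  expect_lt(est$bpnd, 0.02)
  expect_lt(abs(est$R1 - 0.85), 0.01)
})

test_that("NLS estimates vary more in a small low-binding region at matched noise", {
  p <- example_ref_params()
  fs <- short_frame_schedule()
  ref_tac <- ref_curve(fs$frame_mid, p)
  lo <- kinetic_params(0.85, 0.12, 0.4)    # low binding (DBS-like)
  hi <- kinetic_params(0.95, 0.12, 1.8)    # high binding (OC-like)
  mu_lo <- srtm_predict(fs, lo, p)
  mu_hi <- srtm_predict(fs, hi, p)
  set.seed(17)
  ests <- replicate(25, {
    # matched absolute noise; the low-binding signal is relatively weaker
    y_lo <- mu_lo + rnorm(nrow(fs), 0, 0.15)
    y_hi <- mu_hi + rnorm(nrow(fs), 0, 0.15)
    c(lo = fit_srtm_nls(y_lo, ref_tac, fs, n_starts = 2, seed = 1)$bpnd,
      hi = fit_srtm_nls(y_hi, ref_tac, fs, n_starts = 2, seed = 1)$bpnd)
  })
  expect_gt(sd(ests["lo", ]) / 0.4, sd(ests["hi", ]) / 1.8)
})

make_lme_table <- function(shift = 0, n_per_group = 6, seed = 1) {
  set.seed(seed)
  regions <- c("FC", "HIP", "DBS")
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grid <- expand.grid(subject = subj, region = regions,
                      session = c("pre", "post"), stringsAsFactors = FALSE)
  grid$group <- ifelse(match(grid$subject, subj) <= n_per_group, "HV", "MDD")
  grid$arm <- ifelse(grid$group == "HV", "placebo", "active")
  base <- rnorm(length(subj), 0, 0.2)[match(grid$subject, subj)] +
    c(FC = 0.2, HIP = -0.3, DBS = -0.8)[grid$region]
  grid$logbpnd <- base + rnorm(nrow(grid), 0, 0.03) +
    shift * (grid$session == "post") * (grid$arm == "active")
  grid
}

test_that("LME contrast recovers an injected shift and is invariant to duplication", {
  tab <- make_lme_table(shift = 0.07)
  res <- fit_lme_contrast(tab)
  expect_lt(abs(res$estimate - 0.07), 0.04)
  expect_lt(res$p, 0.05)
  # duplicating all rows leaves the point estimate unchanged
  res2 <- fit_lme_contrast(rbind(tab, tab))
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-6)
  # exactly equal session changes in both arms: contrast 0
  tab0 <- make_lme_table(shift = 0)
  tab0$logbpnd <- tab0$logbpnd + 0.05 * (tab0$session == "post")
  res0 <- fit_lme_contrast(tab0)
  expect_lt(abs(res0$estimate), 0.03)
})

test_that("balanced-design oracle: the DiD coefficient equals the cell-mean contrast", {
  tab <- make_lme_table(shift = 0.04, seed = 5)
  res <- fit_lme_contrast(tab)
  cm <- tapply(tab$logbpnd, list(tab$arm, tab$session), mean)
  oracle <- (cm["active", "post"] - cm["active", "pre"]) -
    (cm["placebo", "post"] - cm["placebo", "pre"])
  expect_equal(res$estimate, unname(oracle), tolerance = 1e-6)
})

test_that("power/FPR estimation is calibrated on a Monte-Carlo null", {
  set.seed(21)
  n <- 500
  z <- rnorm(n)
  res <- tibble::tibble(estimate = z, se = 1,
                        p = 2 * pnorm(-abs(z)))
  emp <- estimate_power_fpr(res, method = "empirical")
  expect_true(emp$ci[1] <= 0.05 && 0.05 <= emp$ci[2])
  den <- estimate_power_fpr(res, method = "density", seed = 2)
  expect_lt(abs(den$rate - emp$rate), 0.02)
  # all replicates significant: power 1
  allsig <- tibble::tibble(estimate = 10, se = 1, p = 1e-8)
  expect_equal(estimate_power_fpr(allsig, method = "empirical")$rate, 1)
  # degenerate identical statistics fall back to the empirical estimate
  degen <- tibble::tibble(estimate = rep(2.5, 20), se = 1, p = rep(0.012, 20))
  expect_match(estimate_power_fpr(degen, method = "density")$method, "empirical")
})
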