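# small deterministic dataset shared by the model-layer tests
make_model_data <- function(n_hv = 2, n_pat = 2, regions = c("FC", "HIP", "DBS"),
                            sessions = c("pre", "post"), seed = 31) {
  lib <- build_reference_library(n = 6, frames = short_frame_schedule(),
                                 n_starts = 4, seed = seed)
  pop <- subset_regions(population_params(), regions)
  des <- study_design(n_hv = n_hv, n_patient = n_pat, sessions = sessions)
  study <- simulate_dataset(pop, des, lib, seed = seed)
  list(study = study, dat = as_simba_data(study))
}

md <- make_model_data()

test_that("build_design emits the documented covariate structure", {
  design <- build_design(md$dat)
  # k - 1 region columns for logR1 and logBPND
  expect_equal(sum(design$classes$logR1 == "region"), 2)
  expect_equal(sum(design$classes$logBPND == "region"), 2)
  # logk2prime: age only (single centre)
  expect_identical(design$classes$logk2prime, "age")
  # clinical terms on logBPND: mdd, age x mdd, session, treatment DiD
  expect_true(all(c("mdd", "age_c:mdd", "session_post", "session_post:active")
                  %in% colnames(design$X$logBPND)))
  # single-centre: no centre columns anywhere
  expect_false(any(grepl("centre", unlist(lapply(design$X, colnames)))))
  # age in centred decades: mean 0, scaled by 10 years
  tt <- design$tac_tab
  expect_equal(mean(tt$age_c[!duplicated(tt$meas_id)]), 0, tolerance = 1e-10)
  expect_equal(diff(range(tt$age_c)) * 10, diff(range(tt$age)))
  # sigma skeleton: 3 centred-log covariates + spline basis of dimension 8
  expect_equal(colnames(design$sigma$X), c("clog_dur", "clog_vol", "clog_dose"))
  expect_equal(abs(colMeans(design$sigma$X)), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ncol(design$sigma$spline), 7)  # dimension 8 minus the absorbed constant
})

test_that("age centring example: a 30-year-old in a mean-age-50 cohort scores -2 decades", {
  expect_equal((30 - 50) / 10, -2)
  dat <- md$dat
  dat$meta$age <- c(30, rep(55, nrow(dat$meta) - 2), 45)
  dat$meta$age <- dat$meta$age * 0 + 50 + (dat$meta$age - mean(dat$meta$age))
  dat$meta$age[1] <- 30
  dat$meta$age[-1] <- (50 * nrow(dat$meta) - 30) / (nrow(dat$meta) - 1)
  design <- build_design(dat)
  tt <- design$tac_tab
  expect_equal(unique(tt$age_c[tt$subject == tt$subject[1]])[1], -2,
               tolerance = 1e-10)
})

test_that("multi-centre datasets add centre and centre x region columns", {
  dat <- md$dat
  half <- dat$meta$meas_id[seq_len(nrow(dat$meta) / 2)]
  dat$meta$centre <- ifelse(dat$meta$meas_id %in% half, "KI", "NRU")
  design <- build_design(dat)
  for (p in c("logR1", "logk2prime", "logBPND")) {
    expect_true(any(design$classes[[p]] == "centre"))
  }
  expect_true(any(design$classes$logR1 == "centre_region"))
  expect_equal(sum(design$classes$logR1 == "centre_region"), 2)  # (k-1) x (c-1)
})

test_that("missing metadata is reported by field name", {
  dat <- md$dat
  dat$meta$age[2] <- NA
  expect_error(build_design(dat), "age")
  dat2 <- md$dat
  dat2$regions$volume[1] <- NA
  expect_error(build_design(dat2), "region_volumes")
})

test_that("sigma_predict is log-linear with exact covariate arithmetic", {
  design <- build_design(md$dat)
  sp0 <- list(kappa0 = log(0.2))
  expect_equal(sigma_predict(design, sp0), rep(0.2, nrow(design$obs)))
  # doubling frame duration changes log sigma by exactly beta_dur * ln 2
  sp <- list(kappa0 = log(0.2), beta = c(-0.5, 0, 0))
  s1 <- sigma_predict(design, sp)
  design2 <- design
  design2$sigma$X[, "clog_dur"] <- design$sigma$X[, "clog_dur"] + log(2)
  s2 <- sigma_predict(design2, sp)
  expect_equal(log(s2) - log(s1), rep(-0.5 * log(2), nrow(design$obs)))
  # randomized coefficients match a term-by-term summation oracle
  set.seed(4)
  spr <- list(kappa0 = rnorm(1), beta = rnorm(3), spline = rnorm(7),
              u_meas = rnorm(design$n_meas), u_region = rnorm(design$n_region))
  got <- sigma_predict(design, spr)
  obs <- design$obs
  oracle <- exp(spr$kappa0 +
                  as.vector(design$sigma$X %*% spr$beta) +
                  as.vector(design$sigma$spline %*% spr$spline) +
                  spr$u_meas[obs$meas_idx] + spr$u_region[obs$region_idx])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got > 0))
})

test_that("log_likelihood equals a naive frame-by-frame oracle", {
  dat <- md$dat
  design <- build_design(dat)
  set.seed(9)
  pars <- list(alpha = c(logR1 = log(0.9), logk2prime = log(0.11),
                         logBPND = log(0.8)),
               beta = list(logR1 = rnorm(ncol(design$X$logR1), 0, 0.1),
                           logk2prime = rnorm(ncol(design$X$logk2prime), 0, 0.05),
                           logBPND = rnorm(ncol(design$X$logBPND), 0, 0.1)),
               tau = matrix(rnorm(design$n_subject * 3, 0, 0.05), ncol = 3),
               upsilon_k2p = rnorm(design$n_region, 0, 0.05),
               slope = rnorm(design$n_region, 0, 0.02),
               phi = matrix(rnorm(design$n_tac * 3, 0, 0.02), ncol = 3))
  sig <- list(kappa0 = log(0.15), beta = c(-0.4, -0.3, -0.2),
              spline = rnorm(7, 0, 0.1))
  got <- log_likelihood(dat, design, pars, sig)
  # naive oracle: rebuild every TAC prediction independently and sum dnorm
  theta <- simbaref:::.theta_matrix(design, pars)
  sigma <- sigma_predict(design, sig)
  obs <- design$obs
  tt <- design$tac_tab
  acc <- 0
  for (i in seq_len(design$n_tac)) {
    sel <- which(obs$tac_idx == i)
    fr <- frame_schedule(obs$frame_mid[sel] - obs$frame_duration[sel] / 2,
                         obs$frame_duration[sel])
    kp <- kinetic_params(exp(theta[i, 1]), exp(theta[i, 2]), exp(theta[i, 3]))
    mu <- srtm_predict(fr, kp, dat$ref_params[[tt$meas_id[i]]])
    acc <- acc + sum(dnorm(obs$y[sel], mu, sigma[sel], log = TRUE))
  }
  expect_equal(got, acc, tolerance = 1e-10)
  # zero-residual single observation: -0.5 log(2 pi sigma^2)
  expect_equal(dnorm(0, 0, 0.3, log = TRUE), -0.5 * log(2 * pi * 0.09))
  # doubling sigma with zero residual costs exactly ln 2 per observation
  sig2 <- sig; sig2$kappa0 <- sig$kappa0 + log(2)
  mu_all <- simbaref:::.predict_all_tacs(dat, design, theta)
  dat0 <- dat; dat0$tacs$y <- mu_all
  design0 <- build_design(dat0)
  l1 <- log_likelihood(dat0, design0, pars, sig)
  l2 <- log_likelihood(dat0, design0, pars, sig2)
  expect_equal(l1 - l2, nrow(design$obs) * log(2), tolerance = 1e-8)
})

test_that("compiled objective matches the independent R likelihood", {
  dat <- md$dat
  design <- build_design(dat)
  priors <- default_priors()
  asm <- simbaref:::.assemble_tmb(dat, design, priors)
  obj <- TMB::MakeADFun(data = asm$data, parameters = asm$pars,
                        DLL = "simbaref", silent = TRUE)
  obj$env$beSilent()
  asm0 <- simbaref:::.assemble_tmb(dat, design, priors, likelihood = FALSE)
  obj0 <- TMB::MakeADFun(data = asm0$data, parameters = asm0$pars,
                         DLL = "simbaref", silent = TRUE)
  obj0$env$beSilent()
  set.seed(12)
  q <- obj$par + rnorm(length(obj$par), 0, 0.04)
  lab <- asm$labels
  pn <- c("logR1", "logk2prime", "logBPND")
  grab <- function(re) q[grep(re, lab)]
  tau <- matrix(grab("^tau\\["), ncol = 3)
  phi_r1 <- grab("^phi\\[\\d+,logR1\\]")
  phi_bp <- grab("^phi\\[\\d+,logBPND\\]")
  cpc <- tanh(grab("^cpc_tac"))
  sdt <- priors$tac_scale
  y1 <- phi_r1 / sdt
  phi_k2p <- sdt * grab("^z_phi_k2p")    # r1_bpnd mode: independent margin
  pars <- list(alpha = setNames(grab("^alpha"), pn),
               beta = list(logR1 = grab("^b_logR1"),
                           logk2prime = grab("^b_logk2prime"),
                           logBPND = grab("^b_logBPND")),
               tau = tau,
               upsilon_k2p = grab("^u_reg_k2p"),
               slope = grab("^u_slope"),
               phi = cbind(phi_r1, phi_k2p, phi_bp))
  sig <- list(kappa0 = q[lab == "kappa0"], beta = grab("^beta_sig"),
              spline = grab("^b_spl"), u_meas = grab("^u_sig_meas"),
              u_region = grab("^u_sig_reg"))
  llR <- log_likelihood(dat, design, pars, sig)
  llC <- -(as.numeric(obj$fn(q)) - as.numeric(obj0$fn(q)))
  expect_equal(llC, llR, tolerance = 1e-6)
})

test_that("the stated prior scales are exposed verbatim", {
  pr <- default_priors()
  expect_equal(pr$sd_alpha, 0.25)
  expect_equal(unname(pr$subject_scales), c(0.3, 0.1, 0.3))
  expect_equal(pr$tac_scale, 0.025)
  expect_equal(pr$sd_age, 0.1)
  expect_equal(pr$sd_clinical, 0.05)
  expect_equal(pr$sd_centre, 0.1)
  expect_equal(pr$sd_centre_region, 0.1)
  expect_equal(pr$lkj_eta, 2)
})

test_that("prior-predictive subject deviations respect the half-normal hyperprior", {
  # marginal deviation = half-normal(0.3) scale mixture of normals: its SD is
  # bounded by the scale itself (E[sd^2] = 0.3^2) -- check by simulation
  set.seed(6)
  sds <- abs(rnorm(10000, 0, 0.3))
  dev <- rnorm(10000, 0, sds)
  expect_lt(sd(dev), 0.6)
  expect_equal(sd(dev), 0.3, tolerance = 0.02)
})

test_that("contrast arithmetic: zero weights and linearity of expectation", {
  fit <- list(draws = cbind("b_logBPND[mdd]" = rnorm(200, -0.05, 0.02),
                            "b_logBPND[session_post]" = rnorm(200, 0.01, 0.02)),
              labels = c("b_logBPND[mdd]", "b_logBPND[session_post]"))
  class(fit) <- "simba_posterior"
  z <- contrast_estimate(fit, c("b_logBPND[mdd]" = 0))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)
  w <- c("b_logBPND[mdd]" = 2, "b_logBPND[session_post]" = -1)
  ce <- contrast_estimate(fit, w)
  expect_equal(ce$mean,
               2 * mean(fit$draws[, 1]) - mean(fit$draws[, 2]),
               tolerance = 1e-12)
  expect_error(contrast_estimate(fit, c(nonexistent = 1)), "unknown")
})
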