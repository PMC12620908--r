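make_tac_table <- function(frames = short_frame_schedule(), seed = 1) {
  p <- example_ref_params()
  set.seed(seed)
  tacs <- cbind(FC = ref_curve(frames$frame_mid, p) * 0.9 + rnorm(nrow(frames), 0, 0.05),
                HIP = ref_curve(frames$frame_mid, p) * 1.1 + rnorm(nrow(frames), 0, 0.05))
  structure(list(frames = frames, tacs = tacs,
                 ref = ref_curve(frames$frame_mid, p),
                 meta = list(meas_id = "m01", subject = "s01", group = "HV",
                             centre = "KI", session = "pre", arm = "placebo",
                             age = 34.5, dose = 351.2,
                             region_volumes = list(FC = 50, HIP = 7))),
            class = "tac_table")
}

test_that("TAC tables round-trip through TSV + JSON sidecar", {
  x <- make_tac_table()
  path <- file.path(withr::local_tempdir(), "m01.tsv")
  write_tacs(x, path)
  y <- read_tacs(path)
  expect_equal(y$frames$frame_mid, x$frames$frame_start + x$frames$frame_duration / 2)
  expect_equal(y$tacs, x$tacs, tolerance = 1e-9)
  expect_equal(y$ref, x$ref, tolerance = 1e-9)
  expect_equal(y$meta$age, x$meta$age)
  # second round trip is byte-identical
  path2 <- file.path(withr::local_tempdir(), "m01b.tsv")
  write_tacs(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema violations are reported with the offending columns/fields", {
  x <- make_tac_table()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m01.tsv")
  write_tacs(x, path)
  tab <- read.delim(path)
  tab$reference <- NULL
  write.table(tab, file.path(dir, "noref.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  file.copy(file.path(dir, "m01.json"), file.path(dir, "noref.json"))
  expect_error(read_tacs(file.path(dir, "noref.tsv")), "reference")
  meta <- x$meta; meta$age <- NULL
  jsonlite::write_json(meta, file.path(dir, "m01.json"), auto_unbox = TRUE)
  expect_error(read_tacs(path), "age")
  expect_error(read_tacs(file.path(dir, "absent.tsv")), "no such file")
})

test_that("rmse_and_r matches direct formula recomputation and handles edge cases", {
  set.seed(5)
  truth <- rnorm(20, 2, 0.5)
  est <- truth + rnorm(20, 0, 0.2)
  df <- tibble::tibble(method = "nls", region = "FC", parameter = "bpnd",
                       estimate = est, truth = truth)
  df2 <- dplyr::mutate(df, method = "simba", estimate = truth + (est - truth) / 2)
  rep <- rmse_and_r(dplyr::bind_rows(df, df2))
  direct_rmse <- sqrt(mean((est - truth)^2))
  row <- rep[rep$method == "nls", ]
  expect_equal(row$rmse, direct_rmse, tolerance = 1e-12)
  expect_equal(row$r, cor(est, truth), tolerance = 1e-12)
  srow <- rep[rep$method == "simba", ]
  expect_equal(srow$rmse_reduction_pct, 100 * (1 - srow$rmse / direct_rmse),
               tolerance = 1e-12)
  # estimates == truth
  ident <- rmse_and_r(tibble::tibble(method = "nls", region = "A",
                                     parameter = "bpnd", estimate = 1:5,
                                     truth = 1:5))
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r, 1)
  # constant offset: rmse = |c|, r = 1
  off <- rmse_and_r(tibble::tibble(method = "nls", region = "A",
                                   parameter = "bpnd",
                                   estimate = c(1, 2, 4) + 0.3,
                                   truth = c(1, 2, 4)))
  expect_equal(off$rmse, 0.3)
  expect_equal(off$r, 1)
  # < 3 pairs: r undefined, not NaN
  two <- rmse_and_r(tibble::tibble(method = "nls", region = "A",
                                   parameter = "bpnd", estimate = 1:2,
                                   truth = 2:3))
  expect_true(is.na(two$r) && !is.nan(two$r))
  # row order invariance
  shuf <- rmse_and_r(df[sample(nrow(df)), ])
  expect_equal(shuf$rmse, direct_rmse, tolerance = 1e-12)
})

test_that("icc3k matches the ANOVA mean-squares formula and known limits", {
  # identical raters: perfect consistency
  m <- matrix(rep(c(1, 3, 5, 9), 3), ncol = 3)
  expect_equal(icc3k(m)$icc, 1)
  # hand-computable 4 x 3 table via the mean-squares identity
  set.seed(9)
  m2 <- matrix(rnorm(12, rep(c(0, 2, 4, 6), 3), 1), ncol = 3)
  res <- icc3k(m2)
  a <- anova(lm(y ~ unit + rater,
                data = data.frame(y = as.vector(m2),
                                  unit = factor(rep(1:4, 3)),
                                  rater = factor(rep(1:3, each = 4)))))
  msr <- a["unit", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
  expect_equal(res$icc, (msr - mse) / msr, tolerance = 1e-12)
  expect_true(res$ci[1] < res$icc && res$icc < res$ci[2])
  # large-sample variance-component limit: ICC -> var_u / (var_u + var_e/k)
  set.seed(31)
  n <- 2000; k <- 3
  u <- rnorm(n, 0, 1)
  mm <- sapply(1:k, function(j) u + rnorm(n, 0, 0.8))
  expect_equal(icc3k(mm)$icc, 1 / (1 + 0.8^2 / k), tolerance = 0.05)
  expect_error(icc3k(m[1:2, ]), ">= 3 units")
  # identical units (only rater offsets): zero between-unit variance
  expect_warning(z <- icc3k(matrix(rep(c(1, 2, 3), each = 4), 4, 3)),
                 "zero between-unit")
  expect_equal(z$icc, 0)
})

test_that("se_reduction computes element-wise reductions with summaries", {
  r <- se_reduction(c(0.5, 1, 0.25), c(1, 1, 0.5))
  expect_equal(r$reduction_pct, c(50, 0, 50))
  expect_equal(r$mean, 100 * mean(1 - c(0.5, 1, 0.5)))
  expect_equal(r$range, c(0, 50))
  expect_warning(r0 <- se_reduction(1, 0), "baseline")
  expect_true(is.na(r0$reduction_pct))
})

test_that("linear predictor reproduces the proportional-deviation arithmetic", {
  # +0.3 subject deviation = 35% increase
  expect_equal(exp(0.3), 1.35, tolerance = 0.005)
  lpA <- linear_predictor(log(0.1), subject_dev = 0.3)
  lpB <- linear_predictor(log(3), subject_dev = 0.3)
  expect_equal(lpA$value, 0.1 * exp(0.3))
  expect_equal(round(lpA$value, 2), 0.13)
  expect_equal(signif(lpB$value, 2), 4.0)
  # intercept-only
  expect_equal(linear_predictor(log(2))$value, 2)
  # covariate sum on the log scale
  lp <- linear_predictor(0.5, covariates = c(1, 2), coefficients = c(0.1, -0.05),
                         tac_dev = 0.02)
  expect_equal(lp$log_value, 0.5 + 0.1 - 0.1 + 0.02)
})
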