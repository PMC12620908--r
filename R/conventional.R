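# Conventional two-stage pipeline: per-TAC SRTM NLS with a measured
# (interpolated) reference curve, LME analysis of logBPND, and replicate
# power / false-positive-rate evaluation.

# numerical convolution of a gridded curve with exp(-th t) (FFT, padded)
.grid_conv_exp <- function(f, th, tg) {
  dt <- tg[2] - tg[1]
  n <- length(f)
  N <- stats::nextn(2L * n, 2)
  g <- exp(-th * tg)
  out <- Re(stats::fft(stats::fft(c(f, rep(0, N - n))) *
                         stats::fft(c(g, rep(0, N - n))), inverse = TRUE))[1:n] / N
  out * dt - dt / 2 * (f[1] * g + g[1] * f)   # trapezoid end-correction
}

#' Conventional per-TAC SRTM estimation by nonlinear least squares
#'
#' Field-standard two-stage quantification: the measured reference TAC is
#' linearly interpolated onto a fine grid (zero origin appended), the SRTM
#' convolution term is evaluated by numerical convolution on that grid, and
#' bounded weighted least squares (multi-start Levenberg-Marquardt) fits
#' (R1, k2prime, BPND) per TAC. This path deliberately does not use the
#' analytic Feng-1TC representation: it is the comparison arm.
#'
#' @param tac Target activities per frame.
#' @param ref_tac Measured reference activities on the same frame schedule.
#' @param frames The shared [frame_schedule()].
#' @param bounds List with `lower`/`upper` over (R1, k2prime, bpnd).
#' @param n_starts Random initialisations (first start is a standard
#'   midpoint guess).
#' @param weights Per-frame weights; defaults to frame durations.
#' @param seed Seed for the random starts.
#' @param grid_dt Fine-grid step for the numerical convolution (minutes).
#' @return An `nls_estimate`: list with `R1`, `k2prime`, `bpnd`, `rss`,
#'   `converged`.
#' @export
fit_srtm_nls <- function(tac, ref_tac, frames,
                         bounds = list(lower = c(R1 = 0.1, k2prime = 0.005, bpnd = 0),
                                       upper = c(R1 = 3, k2prime = 1, bpnd = 20)),
                         n_starts = 5, weights = NULL, seed = 1,
                         grid_dt = 0.05) {
  frames <- .assert_frame_schedule(frames)
  stopifnot(length(tac) == nrow(frames), length(ref_tac) == nrow(frames))
  if (is.null(weights)) weights <- frames$frame_duration
  w <- sqrt(weights / mean(weights))
  t_end <- max(frames$frame_mid)
  tg <- seq(0, t_end, by = grid_dt)
  refg <- stats::approx(c(0, frames$frame_mid), c(0, ref_tac), xout = tg,
                        rule = 2)$y
  idx <- pmin(pmax(round(frames$frame_mid / grid_dt) + 1, 1), length(tg))

  predict_nls <- function(par) {
    R1 <- par[1]; k2p <- par[2]; bp <- par[3]
    k2 <- R1 * k2p
    k2a <- k2 / (1 + bp)
    conv <- .grid_conv_exp(refg, k2a, tg)
    (R1 * refg + (k2 - R1 * k2a) * conv)[idx]
  }
  resid_fn <- function(par) w * (tac - predict_nls(par))

  lower <- bounds$lower; upper <- bounds$upper
  starts <- rbind(c(1, 0.1, 1),
                  if (n_starts > 1) {
                    withr_seed(seed, matrix(stats::runif(3 * (n_starts - 1),
                                                         rep(lower, n_starts - 1),
                                                         rep(upper, n_starts - 1)),
                                            ncol = 3, byrow = TRUE))
                  })
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = unname(lower),
                         upper = unname(upper), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(R1 = NA_real_, k2prime = NA_real_, bpnd = NA_real_,
                          rss = Inf, converged = FALSE), class = "nls_estimate"))
  }
  par <- stats::coef(best)
  structure(list(R1 = par[1], k2prime = par[2], bpnd = par[3],
                 rss = best$deviance, converged = best$info %in% 1:4),
            class = "nls_estimate")
}

#' Fit every TAC of a dataset by conventional NLS
#'
#' @param data A `simba_data` object.
#' @param ... Passed to [fit_srtm_nls()].
#' @return Tibble with one row per TAC: identifiers and NLS estimates.
#' @export
nls_study <- function(data, ...) {
  stopifnot(inherits(data, "simba_data"))
  rows <- list()
  for (m in seq_len(nrow(data$meta))) {
    id <- data$meta$meas_id[m]
    sel <- data$tacs$meas_id == id
    sub <- data$tacs[sel, ]
    regions <- unique(sub$region)
    fr <- frame_schedule(sub$frame_mid[sub$region == regions[1]] -
                           sub$frame_duration[sub$region == regions[1]] / 2,
                         sub$frame_duration[sub$region == regions[1]])
    ref_tac <- data$ref_curves[[id]]
    if (is.null(ref_tac)) {
      stop("dataset carries no measured reference curves", call. = FALSE)
    }
    for (r in regions) {
      est <- fit_srtm_nls(sub$y[sub$region == r], ref_tac, fr, ...)
      rows[[length(rows) + 1]] <- tibble::tibble(
        meas_id = id, subject = data$meta$subject[m],
        group = data$meta$group[m], session = data$meta$session[m],
        arm = data$meta$arm[m], region = r,
        R1 = est$R1, k2prime = est$k2prime, bpnd = est$bpnd,
        rss = est$rss, converged = est$converged)
    }
  }
  dplyr::bind_rows(rows)
}

#' Linear mixed-effects analysis of logBPND
#'
#' Second stage of the conventional pipeline: a linear mixed model of
#' logBPND on diagnosis, session and the session x active-arm interaction
#' (the treatment-minus-placebo difference-in-difference), with random
#' intercepts for subject and region. Returns the difference-in-difference
#' coefficient with its standard error and Satterthwaite p-value (falling
#' back to a Wald normal approximation if degrees of freedom are
#' unavailable). Singular fits fall back to a subject-only random
#' structure.
#'
#' @param estimates Tibble with columns `subject`, `region`, `session`,
#'   `arm`, `group` and `bpnd` (natural scale; log taken internally) or
#'   `logbpnd`.
#' @return List with `estimate`, `se`, `p`, `singular`, `model`.
#' @export
fit_lme_contrast <- function(estimates) {
  df <- as.data.frame(estimates)
  if (!"logbpnd" %in% names(df)) {
    if (!"bpnd" %in% names(df)) stop("need `bpnd` or `logbpnd`", call. = FALSE)
    if (any(!is.finite(df$bpnd) | df$bpnd <= 0)) {
      df <- df[is.finite(df$bpnd) & df$bpnd > 0, ]
    }
    df$logbpnd <- log(df$bpnd)
  }
  if (length(unique(df$subject)) < 4) {
    stop("at least 2 subjects per group are required", call. = FALSE)
  }
  sessions <- unique(df$session)
  df$post <- as.numeric(df$session != sessions[1])
  df$active <- as.numeric(df$arm == "active")
  df$mdd <- as.numeric(df$group != "HV")

  fit1 <- suppressMessages(suppressWarnings(
    lmerTest::lmer(logbpnd ~ mdd + post + post:active +
                     (1 | subject) + (1 | region), data = df)))
  singular <- lme4::isSingular(fit1, tol = 1e-5)
  if (singular) {
    fit1 <- suppressMessages(suppressWarnings(
      lmerTest::lmer(logbpnd ~ mdd + post + post:active + (1 | subject),
                     data = df)))
  }
  co <- summary(fit1)$coefficients
  row <- co["post:active", ]
  p <- if ("Pr(>|t|)" %in% colnames(co)) row[["Pr(>|t|)"]] else {
    2 * stats::pnorm(-abs(row[["Estimate"]] / row[["Std. Error"]]))
  }
  list(estimate = unname(row[["Estimate"]]), se = unname(row[["Std. Error"]]),
       p = unname(p), singular = singular, model = fit1)
}

#' Power / false-positive rate over replicate analyses
#'
#' Summarises replicate decision outcomes either empirically (rejection
#' fraction with an exact binomial 95% CI) or via a smooth density fitted
#' to the replicate test statistics: the rejection probability is the tail
#' mass of a Gaussian-kernel density beyond the two-sided normal critical
#' value, with a bootstrap CI over replicates. For Bayesian replicates a
#' posterior tail probability below `alpha` (i.e. the 1 - alpha credible
#' interval excluding zero) counts as a rejection.
#'
#' @param results Tibble of replicate results with columns `estimate`, `se`
#'   and `p` (frequentist p-value or Bayesian two-sided tail probability).
#' @param alpha Decision level (default 0.05).
#' @param method `"empirical"` or `"density"`.
#' @param n_boot Bootstrap replicates for the density-method CI.
#' @param seed Seed for the bootstrap.
#' @return List with `rate`, `ci` (95%), `method`, `n`.
#' @export
estimate_power_fpr <- function(results, alpha = 0.05,
                               method = c("empirical", "density"),
                               n_boot = 500, seed = 1) {
  method <- match.arg(method)
  df <- as.data.frame(results)
  stopifnot(all(c("estimate", "se", "p") %in% names(df)))
  n <- nrow(df)
  reject <- df$p < alpha
  if (method == "empirical") {
    bt <- stats::binom.test(sum(reject), n)
    return(list(rate = mean(reject), ci = unname(bt$conf.int),
                method = "empirical", n = n))
  }
  if (n < 10) stop("density method needs >= 10 replicates", call. = FALSE)
  z <- df$estimate / df$se
  if (stats::sd(z) < 1e-12) {
    bt <- stats::binom.test(sum(reject), n)
    return(list(rate = mean(reject), ci = unname(bt$conf.int),
                method = "empirical_fallback", n = n))
  }
  zc <- stats::qnorm(1 - alpha / 2)
  tail_mass <- function(zv) {
    h <- stats::bw.nrd0(zv)
    mean(stats::pnorm((-zc - zv) / h) + stats::pnorm((zv - zc) / h))
  }
  rate <- tail_mass(z)
  boots <- withr_seed(seed, {
    replicate(n_boot, tail_mass(sample(z, n, replace = TRUE)))
  })
  list(rate = rate, ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       method = "density", n = n)
}
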