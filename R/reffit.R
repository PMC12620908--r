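#' Default Feng-1TC fitting bounds
#'
#' Per-parameter lower/upper bounds for [fit_reference()]. Amplitude bounds
#' scale with the data (peak of the measured curve); rate bounds bracket
#' physiological kinetics generously and the three decay-rate boxes are
#' disjoint (`l1` fast, `l2` intermediate, `l3` slow) so every bounded fit
#' satisfies the canonical `l1 >= l2 >= l3` ordering by construction.
#'
#' @param tac Measured reference activities (used only to scale amplitude
#'   bounds).
#' @return A list with numeric vectors `lower` and `upper` (length 9, named).
#' @export
reference_fit_bounds <- function(tac) {
  scale <- max(abs(tac), 1e-3)
  lower <- c(t0 = 0, a1 = 0, a2 = 0, a3 = 0,
             l1 = 0.8, l2 = 0.05, l3 = 0.0005, g = 1e-4, w = 0.005)
  upper <- c(t0 = 3, a1 = 1000 * scale, a2 = 100 * scale, a3 = 100 * scale,
             l1 = 20, l2 = 0.8, l3 = 0.05, g = 10, w = 2)
  list(lower = lower, upper = upper)
}

.ref_model_eval <- function(par, t) {
  p <- list(t0 = par[["t0"]], a1 = par[["a1"]], a2 = par[["a2"]],
            a3 = par[["a3"]], l1 = par[["l1"]], l2 = par[["l2"]],
            l3 = par[["l3"]], g = par[["g"]], w = par[["w"]])
  class(p) <- "ref_curve_params"
  ref_curve(t, p)
}

#' Fit the Feng-1TC model to a measured reference TAC
#'
#' Bounded multi-start nonlinear least squares: starting values are drawn
#' uniformly between the bounds (seeded, reproducible), each start is fitted
#' with Levenberg-Marquardt ([minpack.lm::nls.lm()]), and the lowest weighted
#' residual sum of squares wins. Decay rates of the returned parameters are
#' re-ordered canonically. The fitted parameters are a curve description, not
#' biology: curve recovery, not parameter identification, is the contract.
#'
#' @param tac Measured reference activities per frame (kBq/mL).
#' @param frames A [frame_schedule()] (at least 10 frames).
#' @param bounds Optional list with `lower`/`upper` length-9 named vectors;
#'   defaults to [reference_fit_bounds()].
#' @param n_starts Number of random initialisations (>= 1, default 20).
#' @param weights Per-frame weights for the residuals; defaults to frame
#'   durations (standard PET weighting).
#' @param seed Integer seed controlling the random starts.
#' @return An object of class `ref_fit`: list with elements `params`
#'   ([ref_curve_params()]), `rss`, `n_starts_used`, `converged`, `qc_flags`
#'   (filled by [qc_reference()]), and `fitted_curve`.
#' @export
fit_reference <- function(tac, frames, bounds = NULL, n_starts = 20,
                          weights = NULL, seed = 1) {
  frames <- .assert_frame_schedule(frames)
  if (length(tac) != nrow(frames)) {
    stop("`tac` length must match the number of frames", call. = FALSE)
  }
  if (nrow(frames) < 10) stop("at least 10 frames are required", call. = FALSE)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  if (is.null(bounds)) bounds <- reference_fit_bounds(tac)
  lower <- bounds$lower
  upper <- bounds$upper
  if (any(!is.finite(c(lower, upper))) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  if (is.null(weights)) weights <- frames$frame_duration
  w <- sqrt(weights / mean(weights))
  t_mid <- frames$frame_mid

  resid_fn <- function(par) w * (tac - .ref_model_eval(par, t_mid))

  best <- NULL
  starts <- withr_seed(seed, {
    matrix(stats::runif(9 * n_starts, rep(lower, n_starts), rep(upper, n_starts)),
           nrow = n_starts, byrow = TRUE, dimnames = list(NULL, names(lower)))
  })
  n_ok <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[s, ], lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    out <- list(params = NULL, rss = Inf, n_starts_used = n_starts,
                converged = FALSE, qc_flags = "fit_failure",
                fitted_curve = rep(NA_real_, length(tac)))
    class(out) <- "ref_fit"
    return(out)
  }
  par <- stats::coef(best)
  params <- as_ref_curve_params(par)
  out <- list(params = params,
              rss = best$deviance,
              n_starts_used = n_starts,
              converged = n_ok > 0L && best$info %in% 1:4,
              qc_flags = character(0),
              fitted_curve = ref_curve(t_mid, params))
  class(out) <- "ref_fit"
  out
}

#' @export
print.ref_fit <- function(x, ...) {
  cat(sprintf("<ref_fit: rss %.4g, %d starts, converged: %s>\n",
              x$rss, x$n_starts_used, x$converged))
  if (length(x$qc_flags)) cat("QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs: exact normal approximation on
# the runs count given n+ positive and n- negative residuals.
.runs_test_p <- function(resid) {
  s <- sign(resid)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(list(runs = 1, p = 0))
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (sigma2 <= 0) return(list(runs = runs, p = 1))
  # one-sided: too few runs indicates structured (underfit) residuals
  list(runs = runs, p = stats::pnorm((runs - mu) / sqrt(sigma2)))
}

#' Quality control for a reference-curve fit
#'
#' Automated surrogates for the visual inspection of Feng-1TC fits. Flags
#' underfitting via (i) a one-sided runs test on signed residuals
#' (structured residuals give too few sign runs; p below `runs_alpha`
#' flags), (ii) peak underestimation beyond `peak_tol` of the measured
#' maximum, and (iii) relative RSS above `rss_multiple` times a supplied
#' cohort median RSS. [plot_ref_fit()] renders the per-fit diagnostic plot
#' for human review.
#'
#' @param fit A `ref_fit` from [fit_reference()].
#' @param tac The measured reference activities the fit was computed from.
#' @param runs_alpha Runs-test significance threshold (default 0.01).
#' @param peak_tol Allowed fractional peak underestimation (default 0.10).
#' @param cohort_median_rss Optional cohort median RSS for the relative-RSS
#'   heuristic.
#' @param rss_multiple Multiple of the cohort median RSS above which the fit
#'   is flagged (default 5).
#' @return The `ref_fit` with `qc_flags` filled and a `qc` element holding
#'   the test details.
#' @export
qc_reference <- function(fit, tac, runs_alpha = 0.01, peak_tol = 0.10,
                         cohort_median_rss = NULL, rss_multiple = 5) {
  stopifnot(inherits(fit, "ref_fit"))
  flags <- character(0)
  resid <- tac - fit$fitted_curve
  runs <- .runs_test_p(resid)
  if (is.finite(runs$p) && runs$p < runs_alpha) flags <- c(flags, "runs_test")
  peak_deficit <- (max(tac) - max(fit$fitted_curve)) / max(tac)
  if (peak_deficit > peak_tol) flags <- c(flags, "peak_underestimation")
  if (!is.null(cohort_median_rss) && is.finite(cohort_median_rss) &&
      cohort_median_rss > 0 && fit$rss > rss_multiple * cohort_median_rss) {
    flags <- c(flags, "high_rss")
  }
  fit$qc_flags <- flags
  fit$qc <- list(runs = runs$runs, runs_p = runs$p, peak_deficit = peak_deficit)
  fit
}

#' Diagnostic plot for a reference-curve fit
#'
#' @param fit A `ref_fit`.
#' @param tac Measured activities.
#' @param frames The [frame_schedule()] used for the fit.
#' @return A ggplot object (measured points, fitted curve, residual panel).
#' @export
plot_ref_fit <- function(fit, tac, frames) {
  frames <- .assert_frame_schedule(frames)
  tg <- seq(0, max(frames$frame_mid), length.out = 300)
  dat <- data.frame(t = frames$frame_mid, measured = tac, fitted = fit$fitted_curve)
  line <- data.frame(t = tg, value = ref_curve(tg, fit$params))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$value), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), colour = "grey40") +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)",
                  title = "Feng-1TC reference fit",
                  subtitle = if (length(fit$qc_flags))
                    paste("QC flags:", paste(fit$qc_flags, collapse = ", "))
                  else "QC: clean") +
    ggplot2::theme_minimal()
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
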