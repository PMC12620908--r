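#' Accuracy report: RMSE and Pearson r against truth
#'
#' Per region x parameter x method root-mean-squared error (absolute
#' accuracy) and Pearson correlation (relative accuracy) of estimates
#' against true values, plus the percentage RMSE reduction of each method
#' relative to a named baseline: `100 * (1 - RMSE_method / RMSE_baseline)`.
#'
#' @param df Tibble with columns `method`, `region`, `parameter`,
#'   `estimate`, `truth`.
#' @param baseline Method name used as the reduction baseline (default
#'   `"nls"`).
#' @return Tibble with `region`, `parameter`, `method`, `n`, `rmse`, `r`,
#'   `rmse_reduction_pct` (NA for the baseline itself). Correlations on
#'   fewer than 3 pairs are reported as NA (undefined), never NaN.
#' @export
rmse_and_r <- function(df, baseline = "nls") {
  stopifnot(all(c("method", "region", "parameter", "estimate", "truth") %in%
                  names(df)))
  out <- df |>
    dplyr::group_by(.data$method, .data$region, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      r = if (dplyr::n() >= 3 && stats::sd(.data$estimate) > 0 &&
              stats::sd(.data$truth) > 0) {
        stats::cor(.data$estimate, .data$truth)
      } else NA_real_,
      .groups = "drop")
  base <- out |>
    dplyr::filter(.data$method == baseline) |>
    dplyr::select("region", "parameter", rmse_base = "rmse")
  out <- dplyr::left_join(out, base, by = c("region", "parameter"))
  out$rmse_reduction_pct <- ifelse(
    out$method == baseline, NA_real_,
    100 * (1 - out$rmse / out$rmse_base))
  dplyr::select(out, -"rmse_base")
}

#' Intraclass correlation ICC(3,k) with F-based confidence interval
#'
#' Two-way mixed-effects, consistency, average-measures intraclass
#' correlation: `(MS_R - MS_E) / MS_R` from the two-way ANOVA mean squares
#' of a units x raters matrix, with the standard F-distribution confidence
#' interval.
#'
#' @param ratings Numeric matrix, rows = units (e.g. regions), columns =
#'   raters (e.g. centres); no missing cells, >= 3 units, >= 2 raters.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci`, `ms_rows`, `ms_error`, `n`, `k`.
#' @export
icc3k <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (any(is.na(m))) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 units and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= .Machine$double.eps) {
    warning("zero between-unit variance; ICC(3,k) is at its lower edge",
            call. = FALSE)
    return(list(icc = 0, ci = c(NA_real_, NA_real_),
                ms_rows = ms_rows, ms_error = ms_err, n = n, k = k))
  }
  icc <- (ms_rows - ms_err) / ms_rows
  if (ms_err <= .Machine$double.eps) {
    return(list(icc = 1, ci = c(1, 1), ms_rows = ms_rows, ms_error = ms_err,
                n = n, k = k))
  }
  alpha <- 1 - conf_level
  Fobs <- ms_rows / ms_err
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  list(icc = icc, ci = c(1 - 1 / FL, 1 - 1 / FU),
       ms_rows = ms_rows, ms_error = ms_err, n = n, k = k)
}

#' Standard-error reduction of one method relative to another
#'
#' `100 * (1 - se_method / se_baseline)` per paired analysis, with mean and
#' range summaries.
#'
#' @param se_method,se_baseline Paired standard errors (e.g. SiMBA vs LME,
#'   one pair per dataset/parameter).
#' @return List with `reduction_pct` (per pair), `mean`, `range`.
#' @export
se_reduction <- function(se_method, se_baseline) {
  stopifnot(length(se_method) == length(se_baseline))
  red <- rep(NA_real_, length(se_method))
  ok <- is.finite(se_baseline) & se_baseline > 0 & is.finite(se_method)
  if (any(!ok)) warning("undefined reductions for zero/non-finite baseline SE",
                        call. = FALSE)
  red[ok] <- 100 * (1 - se_method[ok] / se_baseline[ok])
  list(reduction_pct = red,
       mean = mean(red[ok]),
       range = if (any(ok)) range(red[ok]) else c(NA_real_, NA_real_))
}
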