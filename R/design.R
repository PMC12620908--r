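#' Prior scales for the hierarchical model
#'
#' Returns the full prior specification used by [simba_fit()]. Defaults follow
#' the stated prior policy of the model: normal(mu0, 0.25) on global
#' intercepts of the log-scale PK parameters; zero-centred regularising
#' priors with SD 0.3 for logR1 and logBPND and 0.1 for logk2prime governing
#' subject- and region-level deviations (as half-normal scales on the pooled
#' deviation SDs, and as direct normal SDs on the unpooled region dummies);
#' half-normal 0.025 scales for TAC-level deviation SDs; normal(0, 0.1) on
#' centre, centre x region and age effects; normal(0, 0.05) on diagnosis and
#' treatment effects; and LKJ(eta = 2) on all correlation matrices.
#'
#' The intercept centres `alpha_centre` are radiotracer-neutral placeholders
#' (R1 ~ 0.85, k2prime ~ 0.10 min^-1, BPND ~ 1.0) and should be set per
#' tracer.
#'
#' @param alpha_centre Named numeric: prior means for the three log-scale
#'   intercepts.
#' @param lkj_eta LKJ shape for correlation matrices (default 2).
#' @param kappa0_centre Prior mean for the global log measurement-error level
#'   (log kBq/mL).
#' @param tac_correlation TAC-level correlation structure: `"r1_bpnd"`
#'   (default; correlation between the two per-TAC-identified margins logR1
#'   and logBPND, logk2prime TAC deviations independent) or `"full"` (full
#'   3x3 LKJ structure; its BPND-k2prime partial correlation is very weakly
#'   identified and mixes slowly at short chain lengths).
#' @return A named list of prior scales (class `simba_priors`).
#' @export
default_priors <- function(alpha_centre = c(logR1 = log(0.85),
                                            logk2prime = log(0.10),
                                            logBPND = log(1.0)),
                           lkj_eta = 2,
                           kappa0_centre = log(0.1),
                           tac_correlation = c("r1_bpnd", "full")) {
  tac_correlation <- match.arg(tac_correlation)
  out <- list(
    alpha_centre = alpha_centre,
    sd_alpha = 0.25,
    subject_scales = c(logR1 = 0.3, logk2prime = 0.1, logBPND = 0.3),
    region_scale_k2prime = 0.1,
    tac_scale = 0.025,
    region_dummy_sd = 0.3,
    sd_age = 0.1,
    sd_clinical = 0.05,
    sd_centre = 0.1,
    sd_centre_region = 0.1,
    slope_scale = 0.1,
    lkj_eta = lkj_eta,
    kappa0_centre = kappa0_centre,
    sd_kappa0 = 1,
    sd_sigma_beta = 0.5,
    sd_sigma_spline = 1,
    sigma_meas_scale = 0.3,
    sigma_region_scale = 0.3,
    tac_correlation = tac_correlation
  )
  class(out) <- "simba_priors"
  out
}

# prior SD per fixed-effect column, keyed by the term class recorded when the
# design was built
.beta_prior_sd <- function(classes, priors) {
  unname(c(region = priors$region_dummy_sd,
           age = priors$sd_age,
           clinical = priors$sd_clinical,
           centre = priors$sd_centre,
           centre_region = priors$sd_centre_region)[classes])
}

.region_contrasts <- function(region, coding) {
  f <- factor(region)
  k <- nlevels(f)
  if (k < 2) return(matrix(numeric(0), nrow = length(region), ncol = 0))
  contrasts(f) <- if (coding == "sum") stats::contr.sum(k) else stats::contr.treatment(k)
  X <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(X) <- if (coding == "sum") {
    paste0("region_", levels(f)[seq_len(k - 1)])
  } else {
    paste0("region_", levels(f)[-1])
  }
  X
}

.indicator_matrix <- function(x, prefix) {
  f <- factor(x)
  if (nlevels(f) < 2) return(matrix(numeric(0), nrow = length(x), ncol = 0))
  X <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(X) <- paste0(prefix, "_", levels(f)[-1])
  X
}

#' Build the covariate design for the hierarchical model
#'
#' Assembles, for each log-scale PK parameter, the fixed-effect design matrix
#' and its per-column prior class, plus the skeleton of the measurement-error
#' (sigma) model. Covariate policy: logR1 gets region dummies; logk2prime
#' gets age; logBPND gets region dummies, age, a diagnosis (MDD) indicator
#' and age x MDD interaction when patient data are present, and
#' session/treatment indicators when repeated sessions are present; all three
#' parameters additionally get centre and centre x region terms when the
#' dataset spans multiple centres. Age enters in centred decades
#' ((age - mean age)/10). Region dummies use sum-to-zero coding by default
#' (k - 1 columns either way).
#'
#' The sigma model skeleton holds the three centred natural-log covariates
#' (frame duration, region volume, injected dose) and a thin-plate spline
#' basis over frame time with basis dimension 8.
#'
#' @param data A `simba_data` object (see [simba_data()]).
#' @param region_coding `"sum"` (default) or `"reference"` for the region
#'   dummies.
#' @param random_slopes Attach partially pooled region x age slopes to
#'   logBPND (default TRUE when age varies).
#' @return A `simba_design` object.
#' @export
build_design <- function(data, region_coding = c("sum", "reference"),
                         random_slopes = TRUE) {
  stopifnot(inherits(data, "simba_data"))
  region_coding <- match.arg(region_coding)
  meta <- data$meta
  for (field in c("age", "group", "centre", "session", "arm", "dose")) {
    if (any(is.na(meta[[field]]))) {
      stop("missing metadata field: ", field, call. = FALSE)
    }
  }
  if (any(is.na(data$regions$volume))) {
    stop("missing metadata field: region_volumes", call. = FALSE)
  }

  regions <- data$regions$region
  # one TAC per measurement x region
  tac_tab <- tidyr::expand_grid(meas_id = meta$meas_id, region = regions)
  tac_tab <- dplyr::left_join(tac_tab, meta, by = "meas_id")
  tac_tab$subject_idx <- match(tac_tab$subject, unique(meta$subject))
  tac_tab$meas_idx <- match(tac_tab$meas_id, meta$meas_id)
  tac_tab$region_idx <- match(tac_tab$region, regions)
  tac_tab$tac_id <- paste(tac_tab$meas_id, tac_tab$region, sep = ".")

  age_mean <- mean(meta$age)
  tac_tab$age_c <- (tac_tab$age - age_mean) / 10

  multi_centre <- length(unique(meta$centre)) > 1
  has_patients <- length(unique(tac_tab$group)) > 1
  has_sessions <- length(unique(tac_tab$session)) > 1
  multi_arm <- length(unique(tac_tab$arm)) > 1

  Xreg <- .region_contrasts(tac_tab$region, region_coding)
  centre_cols <- if (multi_centre) {
    Xc <- .indicator_matrix(tac_tab$centre, "centre")
    Xcr <- do.call(cbind, lapply(colnames(Xc), function(cc) {
      M <- Xreg * Xc[, cc]
      colnames(M) <- paste0(cc, ":", colnames(Xreg))
      M
    }))
    list(X = cbind(Xc, Xcr),
         classes = c(rep("centre", ncol(Xc)), rep("centre_region", ncol(Xcr))))
  } else {
    list(X = matrix(numeric(0), nrow(tac_tab), 0), classes = character(0))
  }

  # logR1: region (+ centre terms)
  X1 <- cbind(Xreg, centre_cols$X)
  cls1 <- c(rep("region", ncol(Xreg)), centre_cols$classes)

  # logk2prime: age (+ centre terms); regional deviations are partially pooled
  X2 <- cbind(age_c = tac_tab$age_c, centre_cols$X)
  cls2 <- c("age", centre_cols$classes)

  # logBPND: region + age (+ clinical/session terms) (+ centre terms)
  X3 <- cbind(Xreg, age_c = tac_tab$age_c)
  cls3 <- c(rep("region", ncol(Xreg)), "age")
  baseline_level <- function(x, preferred) {
    lv <- unique(x)
    hit <- lv[lv %in% preferred]
    if (length(hit)) hit[1] else sort(lv)[1]
  }
  if (has_patients) {
    mdd <- as.numeric(tac_tab$group !=
                        baseline_level(tac_tab$group, c("HV", "hv", "control")))
    X3 <- cbind(X3, mdd = mdd, `age_c:mdd` = tac_tab$age_c * mdd)
    cls3 <- c(cls3, "clinical", "clinical")
  }
  if (has_sessions) {
    post <- as.numeric(tac_tab$session !=
                         baseline_level(tac_tab$session, c("pre", "baseline")))
    X3 <- cbind(X3, session_post = post)
    cls3 <- c(cls3, "clinical")
    if (multi_arm) {
      active <- as.numeric(tac_tab$arm == "active")
      X3 <- cbind(X3, `session_post:active` = post * active)
      cls3 <- c(cls3, "clinical")
    }
  }
  X3 <- cbind(X3, centre_cols$X)
  cls3 <- c(cls3, centre_cols$classes)

  # sigma-model skeleton on the observation grid
  tacs <- data$tacs
  obs <- dplyr::left_join(
    tacs,
    dplyr::select(tac_tab, "meas_id", "region", "tac_id", "subject_idx",
                  "meas_idx", "region_idx"),
    by = c("meas_id", "region"))
  obs$tac_idx <- match(obs$tac_id, tac_tab$tac_id)
  vol <- data$regions$volume[obs$region_idx]
  dose <- meta$dose[obs$meas_idx]
  centers <- c(log_dur = mean(log(obs$frame_duration)),
               log_vol = mean(log(vol)),
               log_dose = mean(log(dose)))
  X_sigma <- cbind(clog_dur = log(obs$frame_duration) - centers["log_dur"],
                   clog_vol = log(vol) - centers["log_vol"],
                   clog_dose = log(dose) - centers["log_dose"])
  sm <- mgcv::smoothCon(mgcv::s(frame_mid, bs = "tp", k = 8),
                        data = data.frame(frame_mid = obs$frame_mid),
                        absorb.cons = TRUE)[[1]]
  B <- sm$X
  colnames(B) <- paste0("spline_", seq_len(ncol(B)))

  out <- list(
    tac_tab = tac_tab,
    obs = obs,
    X = list(logR1 = X1, logk2prime = X2, logBPND = X3),
    classes = list(logR1 = cls1, logk2prime = cls2, logBPND = cls3),
    sigma = list(X = X_sigma, spline = B, smooth = sm, centers = centers),
    age_mean = age_mean,
    region_coding = region_coding,
    random_slopes = random_slopes && stats::sd(tac_tab$age_c) > 0,
    regions = regions,
    n_subject = length(unique(meta$subject)),
    n_meas = nrow(meta),
    n_region = length(regions),
    n_tac = nrow(tac_tab)
  )
  class(out) <- "simba_design"
  out
}

#' @export
print.simba_design <- function(x, ...) {
  cat(sprintf(
    "<simba_design: %d TACs (%d measurements x %d regions), %d subjects>\n",
    x$n_tac, x$n_meas, x$n_region, x$n_subject))
  for (p in names(x$X)) {
    cat(sprintf("  %s: %d fixed-effect column(s): %s\n", p, ncol(x$X[[p]]),
                paste(colnames(x$X[[p]]), collapse = ", ")))
  }
  cat(sprintf("  sigma: %d covariates + %d spline columns\n",
              ncol(x$sigma$X), ncol(x$sigma$spline)))
  invisible(x)
}

#' Log-scale linear predictor for one PK parameter
#'
#' The hierarchical decomposition of each log-scale PK parameter is the sum
#' of a global intercept, fixed covariate effects, and partially pooled
#' deviations for the subject, the region, and the TAC. Because the model is
#' on the log scale, an additive deviation is a proportional change on the
#' natural scale: a subject deviation of 0.3 multiplies the expected
#' natural-scale value by exp(0.3) = 1.35.
#'
#' @param alpha Global intercept (log scale).
#' @param covariates,coefficients Matched numeric vectors (covariate values
#'   and their fixed-effect coefficients); may be empty.
#' @param subject_dev,region_dev,tac_dev Deviations (log scale).
#' @return List with `log_value` and natural-scale `value`.
#' @examples
#' # a +0.3 subject deviation is a 35% increase on the natural scale
#' linear_predictor(log(0.1), subject_dev = 0.3)$value   # 0.135
#' @export
linear_predictor <- function(alpha, covariates = numeric(0),
                             coefficients = numeric(0),
                             subject_dev = 0, region_dev = 0, tac_dev = 0) {
  stopifnot(length(covariates) == length(coefficients))
  log_value <- alpha + sum(covariates * coefficients) +
    subject_dev + region_dev + tac_dev
  list(log_value = log_value, value = exp(log_value))
}
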