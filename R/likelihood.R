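# Assemble the n_tac x 3 matrix of log-scale PK parameters from model
# components. `pars` holds alpha (length 3), beta (list of coefficient
# vectors per parameter), tau (n_subject x 3), upsilon_k2p (n_region),
# slope (n_region, age slopes on logBPND), phi (n_tac x 3). Any component
# may be omitted (treated as zero).
.theta_matrix <- function(design, pars) {
  nt <- design$n_tac
  pnames <- c("logR1", "logk2prime", "logBPND")
  theta <- matrix(0, nt, 3, dimnames = list(design$tac_tab$tac_id, pnames))
  tt <- design$tac_tab
  for (i in 1:3) {
    p <- pnames[i]
    th <- rep(pars$alpha[[p]] %||% pars$alpha[i], nt)
    X <- design$X[[p]]
    if (!is.null(pars$beta[[p]]) && ncol(X) > 0) {
      th <- th + drop(X %*% pars$beta[[p]])
    }
    if (!is.null(pars$tau)) th <- th + pars$tau[tt$subject_idx, i]
    if (i == 2 && !is.null(pars$upsilon_k2p)) {
      th <- th + pars$upsilon_k2p[tt$region_idx]
    }
    if (i == 3 && !is.null(pars$slope)) {
      th <- th + pars$slope[tt$region_idx] * tt$age_c
    }
    if (!is.null(pars$phi)) th <- th + pars$phi[, i]
    theta[, i] <- th
  }
  theta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame-level measurement-error prediction
#'
#' Evaluates the log-linear model for the measurement error
#' \eqn{\sigma_{h,j,k}}: a global mean, partially pooled deviations per PET
#' measurement and per region (optionally per TAC), coefficients on the
#' centred natural logs of frame duration, region volume and injected dose,
#' and a thin-plate-spline smooth over frame time (basis dimension 8).
#' The log link guarantees a strictly positive prediction.
#'
#' @param design A `simba_design` from [build_design()].
#' @param sigma_pars List with `kappa0` (global mean of log sigma), `beta`
#'   (coefficients on the three centred-log covariates), `spline`
#'   (coefficients on the spline basis columns), and optional deviation
#'   vectors `u_meas`, `u_region`, `u_tac`.
#' @return Vector of per-observation sigma values (kBq/mL), aligned with
#'   `design$obs`.
#' @export
sigma_predict <- function(design, sigma_pars) {
  stopifnot(inherits(design, "simba_design"))
  obs <- design$obs
  logsig <- rep(sigma_pars$kappa0, nrow(obs))
  if (!is.null(sigma_pars$beta)) {
    logsig <- logsig + drop(design$sigma$X %*% sigma_pars$beta)
  }
  if (!is.null(sigma_pars$spline)) {
    logsig <- logsig + drop(design$sigma$spline %*% sigma_pars$spline)
  }
  if (!is.null(sigma_pars$u_meas)) logsig <- logsig + sigma_pars$u_meas[obs$meas_idx]
  if (!is.null(sigma_pars$u_region)) logsig <- logsig + sigma_pars$u_region[obs$region_idx]
  if (!is.null(sigma_pars$u_tac)) logsig <- logsig + sigma_pars$u_tac[obs$tac_idx]
  exp(unname(logsig))
}

#' Joint log-likelihood of a TAC dataset
#'
#' Sums the normal log-density over every frame of every TAC, with the mean
#' given by the analytic SRTM (or FRTM) prediction at the TAC's PK
#' parameters and the per-frame standard deviation from [sigma_predict()].
#'
#' @param data A `simba_data` object.
#' @param design The matching `simba_design`.
#' @param pars Model parameters (see [sigma_predict()] and the theta
#'   components: `alpha`, `beta`, `tau`, `upsilon_k2p`, `slope`, `phi`).
#' @param sigma_pars Measurement-error parameters for [sigma_predict()].
#' @param model `"srtm"` (default) or `"frtm"`; FRTM additionally requires
#'   `pars$log_k4` (per-TAC vector or scalar).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, design, pars, sigma_pars, model = c("srtm", "frtm")) {
  model <- match.arg(model)
  theta <- .theta_matrix(design, pars)
  obs <- design$obs
  sig <- sigma_predict(design, sigma_pars)
  mu <- .predict_all_tacs(data, design, theta, model = model,
                          log_k4 = pars$log_k4)
  bad <- !is.finite(mu)
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("non-finite prediction for TAC %s at frame t = %.2f min",
                 obs$tac_id[b] %||% design$tac_tab$tac_id[obs$tac_idx[b]],
                 obs$frame_mid[b]), call. = FALSE)
  }
  sum(stats::dnorm(obs$y, mu, sig, log = TRUE))
}

# mu for every observation given the per-TAC theta matrix
.predict_all_tacs <- function(data, design, theta, model = "srtm", log_k4 = NULL) {
  obs <- design$obs
  mu <- numeric(nrow(obs))
  tt <- design$tac_tab
  for (i in seq_len(design$n_tac)) {
    sel <- obs$tac_idx == i
    if (!any(sel)) next
    rp <- data$ref_params[[tt$meas_id[i]]]
    fr <- frame_schedule(obs$frame_mid[sel] - obs$frame_duration[sel] / 2,
                         obs$frame_duration[sel])
    kp <- if (model == "srtm") {
      kinetic_params(exp(theta[i, 1]), exp(theta[i, 2]), exp(theta[i, 3]))
    } else {
      k4i <- exp(if (length(log_k4) > 1) log_k4[i] else log_k4)
      kinetic_params(exp(theta[i, 1]), exp(theta[i, 2]), exp(theta[i, 3]), k4 = k4i)
    }
    mu[sel] <- if (model == "srtm") srtm_predict(fr, kp, rp) else frtm_predict(fr, kp, rp)
  }
  mu
}
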