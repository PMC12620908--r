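#' Reference-tissue pharmacokinetic parameters
#'
#' Container for the per-TAC parameters of the simplified (SRTM) and full
#' (FRTM) reference tissue models, parameterised as relative delivery `R1`,
#' reference-region clearance `k2prime` (min^-1) and binding potential
#' `bpnd`, plus the dissociation rate `k4` (min^-1) for the FRTM. Derived
#' rates are stored alongside: \eqn{k_2 = R_1 k_2'},
#' \eqn{k_{2a} = k_2 / (1 + BP_{ND})} and, for the FRTM,
#' \eqn{k_3 = BP_{ND} k_4}.
#'
#' @param R1 Relative delivery (unitless, > 0).
#' @param k2prime Reference-tissue clearance (min^-1, > 0).
#' @param bpnd Binding potential (unitless, >= 0).
#' @param k4 Dissociation rate (min^-1, > 0); supply only for the FRTM.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(R1 = 0.9, k2prime = 0.12, bpnd = 1.5)
#' kinetic_params(R1 = 0.9, k2prime = 0.12, bpnd = 1.5, k4 = 0.1)
#' @export
kinetic_params <- function(R1, k2prime, bpnd, k4 = NULL) {
  stopifnot(is.finite(R1), is.finite(k2prime), is.finite(bpnd))
  if (R1 <= 0 || k2prime <= 0) stop("`R1` and `k2prime` must be > 0", call. = FALSE)
  if (bpnd < 0) stop("`bpnd` must be >= 0", call. = FALSE)
  out <- list(R1 = R1, k2prime = k2prime, bpnd = bpnd,
              k2 = R1 * k2prime, k2a = R1 * k2prime / (1 + bpnd))
  if (!is.null(k4)) {
    stopifnot(is.finite(k4))
    if (k4 <= 0) stop("`k4` must be > 0 for the FRTM", call. = FALSE)
    out$k4 <- k4
    out$k3 <- bpnd * k4
  }
  class(out) <- "kinetic_params"
  out
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params (%s)>\n", if (is.null(x$k4)) "SRTM" else "FRTM"))
  print(signif(unlist(x), 4))
  invisible(x)
}

.predict_times <- function(frames) {
  frames <- .assert_frame_schedule(frames)
  list(frames = frames,
       mid = frames$frame_mid,
       t1 = frames$frame_start,
       t2 = frames$frame_start + frames$frame_duration)
}

# frame averages of a curve with running integral `integ`: (I(t2)-I(t1))/dur
.frame_average <- function(integ, tt) {
  (integ(tt$t2) - integ(tt$t1)) / tt$frames$frame_duration
}

#' SRTM target-tissue prediction
#'
#' Closed-form simplified reference tissue model prediction
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a}) \, [C_R \otimes e^{-k_{2a} t}](t),}
#' with the convolution resolved analytically through the Feng-1TC
#' representation of the reference curve. By default the model curve is
#' evaluated at frame midpoints; `mode = "frame_average"` instead returns
#' exact analytic averages over each frame interval.
#'
#' @param frames A [frame_schedule()].
#' @param kp A [kinetic_params()] without `k4`.
#' @param p A [ref_curve_params()] for the reference curve.
#' @param mode `"midpoint"` (default) or `"frame_average"`.
#' @return Predicted \eqn{C_T} per frame.
#' @examples
#' fs <- short_frame_schedule()
#' p <- ref_curve_params(0.5, 60, 3, 1, 4, 0.5, 0.02, 0.4, 0.12)
#' srtm_predict(fs, kinetic_params(0.9, 0.12, 1.5), p)
#' @export
srtm_predict <- function(frames, kp, p, mode = c("midpoint", "frame_average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kp, "kinetic_params"), inherits(p, "ref_curve_params"))
  if (!is.null(kp$k4)) {
    stop("`kp` includes k4; use frtm_predict() or drop k4", call. = FALSE)
  }
  tt <- .predict_times(frames)
  coef2 <- kp$k2 - kp$R1 * kp$k2a
  if (mode == "midpoint") {
    kp$R1 * ref_curve(tt$mid, p) + coef2 * .ref_conv_exp(tt$mid, p, kp$k2a)
  } else {
    .frame_average(function(t) {
      kp$R1 * .ref_curve_integral(t, p) +
        coef2 * .ref_conv_exp_integral(t, p, kp$k2a)
    }, tt)
  }
}

# FRTM macro-rates and convolution weights.
# In the Laplace domain C_T/C_R = R1 (s + k3 + k4)(s + k2') / ((s+al)(s+be))
# with al + be = k2 + k3 + k4 and al be = k2 k4, giving
# C_T = R1 [ C_R + (A e^{-al t} + B e^{-be t}) * C_R ].
.frtm_macro <- function(kp) {
  s <- kp$k2 + kp$k3 + kp$k4
  disc <- sqrt(max(s^2 - 4 * kp$k2 * kp$k4, 0))
  al <- (s - disc) / 2
  be <- (s + disc) / 2
  num <- function(r) -(kp$k2prime - kp$k2) * r + (kp$k3 + kp$k4) * kp$k2prime -
    kp$k2 * kp$k4
  denom <- max(be - al, 1e-12)   # repeated macro-roots require k3 = 0, k2 = k4
  list(al = al, be = be, A = num(al) / denom, B = -num(be) / denom)
}

#' FRTM target-tissue prediction
#'
#' Closed-form full reference tissue model prediction using the two
#' macro-rates of the two-tissue characteristic polynomial in
#' \eqn{(k_2, k_3, k_4)}. Reduces to [srtm_predict()] in the
#' rapid-equilibration limit (\eqn{k_4 \to \infty} at fixed \eqn{BP_{ND}}).
#'
#' @inheritParams srtm_predict
#' @param kp A [kinetic_params()] including `k4`.
#' @return Predicted \eqn{C_T} per frame.
#' @export
frtm_predict <- function(frames, kp, p, mode = c("midpoint", "frame_average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kp, "kinetic_params"), inherits(p, "ref_curve_params"))
  if (is.null(kp$k4)) stop("`kp` must include k4 for the FRTM", call. = FALSE)
  tt <- .predict_times(frames)
  m <- .frtm_macro(kp)
  if (mode == "midpoint") {
    kp$R1 * (ref_curve(tt$mid, p) +
               m$A * .ref_conv_exp(tt$mid, p, m$al) +
               m$B * .ref_conv_exp(tt$mid, p, m$be))
  } else {
    .frame_average(function(t) {
      kp$R1 * (.ref_curve_integral(t, p) +
                 m$A * .ref_conv_exp_integral(t, p, m$al) +
                 m$B * .ref_conv_exp_integral(t, p, m$be))
    }, tt)
  }
}
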