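#' Feng-1TC reference-curve parameters
#'
#' The reference-region curve \eqn{C_R(t)} is represented by a nine-parameter
#' "Feng-1TC" model: a Feng-style ramp-plus-tri-exponential input function,
#' delayed by an onset time `t0`, convolved with a one-tissue-compartment
#' impulse response \eqn{g e^{-w t}}. The parameters are a computational
#' device — they make every downstream convolution analytic — and carry no
#' biological interpretation.
#'
#' On shifted time \eqn{u = t - t0} the input is
#' \deqn{f(u) = (a_1 u - a_2 - a_3) e^{-l_1 u} + a_2 e^{-l_2 u} + a_3 e^{-l_3 u},}
#' zero for \eqn{u \le 0} (and continuous at the onset).
#'
#' @param t0 Onset delay (minutes, >= 0); the curve is 0 before `t0`.
#' @param a1 Ramp amplitude (activity min^-1).
#' @param a2,a3 Exponential amplitudes (activity units).
#' @param l1,l2,l3 Decay rates (min^-1); stored in canonical order
#'   `l1 >= l2 >= l3 >= 0` to remove label switching.
#' @param g Amplitude of the one-tissue impulse response (min^-1 scaled, >= 0).
#' @param w Rate of the one-tissue impulse response (min^-1, > 0).
#' @return An object of class `ref_curve_params` (named list of the nine
#'   values).
#' @examples
#' p <- ref_curve_params(t0 = 0.5, a1 = 60, a2 = 3, a3 = 1,
#'                       l1 = 4, l2 = 0.5, l3 = 0.02, g = 0.4, w = 0.12)
#' ref_curve(c(0, 1, 5, 30), p)
#' @export
ref_curve_params <- function(t0, a1, a2, a3, l1, l2, l3, g, w) {
  vals <- c(t0 = t0, a1 = a1, a2 = a2, a3 = a3,
            l1 = l1, l2 = l2, l3 = l3, g = g, w = w)
  if (length(vals) != 9L || any(!is.finite(vals))) {
    stop("exactly nine finite parameter values are required", call. = FALSE)
  }
  if (t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  if (w <= 0) stop("`w` must be > 0", call. = FALSE)
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  ls <- c(l1, l2, l3)
  if (any(ls < 0)) stop("decay rates must be >= 0", call. = FALSE)
  # canonical ordering l1 >= l2 >= l3: the three amplitudes travel with their
  # rates, except a1 which is bound to the ramp term (always the l1 slot).
  ord <- order(ls, decreasing = TRUE)
  if (!identical(ord, 1:3)) {
    # only reorder the pure-exponential slots; the ramp stays with l1 by
    # construction of the fit (bounds enforce l1 fastest), so a full reorder
    # is only valid when the ramp slot remains the largest rate
    if (which.max(ls) != 1L) {
      stop("`l1` (the ramp rate) must be the largest decay rate", call. = FALSE)
    }
    if (l2 < l3) {
      tmp <- l2; l2 <- l3; l3 <- tmp
      tmp <- a2; a2 <- a3; a3 <- tmp
    }
  }
  out <- list(t0 = t0, a1 = a1, a2 = a2, a3 = a3,
              l1 = l1, l2 = l2, l3 = l3, g = g, w = w)
  class(out) <- "ref_curve_params"
  out
}

#' @export
print.ref_curve_params <- function(x, ...) {
  cat("<ref_curve_params (Feng-1TC, 9 parameters)>\n")
  print(signif(unlist(x), 4))
  invisible(x)
}

#' @rdname ref_curve_params
#' @param x For `as_ref_curve_params()`: a named numeric vector or list with
#'   elements `t0, a1, a2, a3, l1, l2, l3, g, w`.
#' @export
as_ref_curve_params <- function(x) {
  x <- unlist(x)
  need <- c("t0", "a1", "a2", "a3", "l1", "l2", "l3", "g", "w")
  if (!all(need %in% names(x))) {
    stop("missing reference-curve parameters: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  do.call(ref_curve_params, as.list(x[need]))
}

#' Feng input function
#'
#' Evaluates the delayed ramp-plus-tri-exponential input underlying the
#' Feng-1TC reference model. Zero for `t <= t0` and continuous at the onset
#' (the amplitudes satisfy \eqn{-a_2 - a_3 + a_2 + a_3 = 0} at \eqn{u = 0}).
#'
#' @param t Times (minutes).
#' @param p A [ref_curve_params()] object.
#' @return Input values at `t` (activity concentration units).
#' @export
feng_input <- function(t, p) {
  stopifnot(inherits(p, "ref_curve_params"))
  u <- t - p$t0
  out <- numeric(length(t))
  pos <- u > 0
  if (any(pos)) {
    uu <- u[pos]
    out[pos] <- (p$a1 * uu - p$a2 - p$a3) * exp(-p$l1 * uu) +
      p$a2 * exp(-p$l2 * uu) + p$a3 * exp(-p$l3 * uu)
  }
  out
}

# Shared assembly: C_R and its convolution with an extra exponential kernel
# are both linear combinations of the same four term families.
#   C_R(t)      = g [ a1 F2(l1,w,u) - (a2+a3) F1(l1,w,u) + a2 F1(l2,w,u) + a3 F1(l3,w,u) ]
#   (C_R * e^{-th .})(t) = same combination with F_k(l, w, u) -> G_k(l, w, th, u)
.ref_terms <- function(p, u, fk1, fk2) {
  p$g * (p$a1 * fk2(p$l1, u) -
           (p$a2 + p$a3) * fk1(p$l1, u) +
           p$a2 * fk1(p$l2, u) +
           p$a3 * fk1(p$l3, u))
}

#' Analytic reference-region curve
#'
#' Evaluates \eqn{C_R(t)}: the Feng input convolved with the one-tissue
#' impulse response \eqn{g e^{-w t}}, resolved entirely in closed form
#' (ramp-times-exponential and exponential-times-exponential kernels).
#' Coincident decay rates are handled by continuous limit forms.
#'
#' @inheritParams feng_input
#' @return \eqn{C_R} values at `t` (kBq/mL for kBq/mL-scaled amplitudes).
#' @export
ref_curve <- function(t, p) {
  stopifnot(inherits(p, "ref_curve_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  u <- pmax(t - p$t0, 0)
  .ref_terms(p, u,
             fk1 = function(l, u) .conv_kernel(l, p$w, u, k = 1L),
             fk2 = function(l, u) .conv_kernel(l, p$w, u, k = 2L))
}

# (C_R * e^{-theta .})(t): the convolution integral of the analytic reference
# curve against a decaying exponential; the workhorse of SRTM/FRTM predictions.
.ref_conv_exp <- function(t, p, theta) {
  u <- pmax(t - p$t0, 0)
  .ref_terms(p, u,
             fk1 = function(l, u) .conv3_kernel(l, p$w, theta, u, k = 1L),
             fk2 = function(l, u) .conv3_kernel(l, p$w, theta, u, k = 2L))
}

# Running integral int_0^t C_R ds, closed form via
# int_0^t conv(f, e^{-w.}) = (1/w) (int_0^t f - conv(f, e^{-w.})(t)).
.ref_curve_integral <- function(t, p) {
  u <- pmax(t - p$t0, 0)
  # int_0^u feng: elementary antiderivatives of (c0 + c1 s) e^{-l s}
  int_exp <- function(l, u) if (l > 0) (1 - exp(-l * u)) / l else u
  int_ramp <- function(l, u) {
    if (l > 0) (1 - (1 + l * u) * exp(-l * u)) / l^2 else u^2 / 2
  }
  int_feng <- p$a1 * int_ramp(p$l1, u) - (p$a2 + p$a3) * int_exp(p$l1, u) +
    p$a2 * int_exp(p$l2, u) + p$a3 * int_exp(p$l3, u)
  (p$g * int_feng - ref_curve(t, p)) / p$w
}

# Running integral int_0^t (C_R * e^{-theta .}) ds, same identity with f = C_R.
.ref_conv_exp_integral <- function(t, p, theta) {
  (.ref_curve_integral(t, p) - .ref_conv_exp(t, p, theta)) / theta
}

#' Locate the peak of the Feng input analytically
#'
#' Solves for the maximiser of the input function from the root of its
#' derivative on the dominant ramp-exponential term, refined over the full
#' analytic derivative with [stats::optimize()].
#'
#' @inheritParams feng_input
#' @param t_max Upper end of the search window (minutes).
#' @return Peak time in minutes.
#' @keywords internal
feng_input_peak <- function(p, t_max = 10) {
  stats::optimize(function(t) feng_input(t, p),
                  interval = c(p$t0, p$t0 + t_max), maximum = TRUE,
                  tol = 1e-8)$maximum
}
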