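# Closed-form convolution kernels for sums of (polynomial x exponential) terms.
#
# Everything the reference-tissue forward models need can be reduced to
#   F_k(a, b, t) = integral_0^t s^(k-1) exp(-a s) exp(-b (t - s)) ds
#               = t^k exp(-b t) phi_k((a - b) t),   phi_k(x) = integral_0^1 u^(k-1) e^(-x u) du
# for k = 1, 2, 3. phi_k is evaluated by its Maclaurin series when |x| is small,
# which contains the coincident-rate limit (x = 0) as its leading term and avoids
# the catastrophic cancellation of the exact expression near degeneracy.

# series switch: below this |x| = |a-b|*t the Maclaurin series (7 terms) is used;
# truncation error there is < 1e-13 relative, and the exact forms are safe above it.
.PHI_SERIES_X <- 0.05

.phi_series <- function(x, k) {
  # sum_{m=0}^{6} (-x)^m / (m! (m + k))
  out <- 1 / k
  term <- rep(1, length(x))
  fact <- 1
  for (m in 1:6) {
    fact <- fact * m
    term <- term * (-x)
    out <- out + term / (fact * (m + k))
  }
  out
}

# F_k(a, b, t); vectorised over t (a, b scalars). Away from degeneracy the
# direct difference forms (in d = a - b) are used; they are overflow-safe for
# either sign of d because every term decays like exp(-min(a,b) t):
#   F_1 = (e^{-bt} - e^{-at}) / d
#   F_2 = (e^{-bt} - (1 + d t) e^{-at}) / d^2
#   F_3 = (2 e^{-bt} - (2 + 2 d t + d^2 t^2) e^{-at}) / d^3
.conv_kernel <- function(a, b, t, k = 1L) {
  d <- a - b
  x <- d * t
  small <- abs(x) < .PHI_SERIES_X
  out <- numeric(length(t))
  if (any(small)) {
    ts <- t[small]
    out[small] <- ts^k * exp(-b * ts) * .phi_series(x[small], k)
  }
  if (any(!small)) {
    tt <- t[!small]
    eb <- exp(-b * tt)
    ea <- exp(-a * tt)
    out[!small] <- switch(k,
      (eb - ea) / d,
      (eb - (1 + d * tt) * ea) / d^2,
      (2 * eb - (2 + 2 * d * tt + (d * tt)^2) * ea) / d^3
    )
  }
  out
}

#' Analytic convolution of two decaying exponentials
#'
#' Computes \eqn{\int_0^t e^{-a s} e^{-b (t - s)} \, ds}, the building block of
#' every closed-form reference-tissue model prediction in this package. The
#' coincident-rate limit \eqn{t e^{-a t}} (for \eqn{a \to b}) is obtained by a
#' series evaluation that is continuous across the degeneracy.
#'
#' @param a,b Non-negative decay rates (min^-1).
#' @param t Non-negative times (minutes); vectorised.
#' @return Kernel values, same length as `t`.
#' @examples
#' exp_conv_exp(0, 0, 7)          # integrand is 1: returns 7
#' exp_conv_exp(1, 1, 2)          # degenerate limit: 2 * exp(-2)
#' exp_conv_exp(0.2, 0.5, 10)
#' @export
exp_conv_exp <- function(a, b, t) {
  if (length(a) != 1L || length(b) != 1L) {
    stop("`a` and `b` must be scalar rates", call. = FALSE)
  }
  if (a < 0 || b < 0) stop("rates `a` and `b` must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  .conv_kernel(a, b, t, k = 1L)
}

# integral_0^t s e^(-a s) e^(-b(t-s)) ds  (ramp x exp against exp)
.ramp_conv_exp <- function(a, b, t) .conv_kernel(a, b, t, k = 2L)

# integral_0^t s^2 e^(-a s) e^(-b(t-s)) ds
.sq_conv_exp <- function(a, b, t) .conv_kernel(a, b, t, k = 3L)

# Triple convolutions against two outer exponential kernels exp(-w t), exp(-th t):
#   G_k(l, w, th, t) = (s^(k-1) e^{-l s}) * e^{-w .} * e^{-th .}
# resolved through G_k = (F_k(l, th, t) - F_k(l, w, t)) / (w - th), with the
# w ~= th limit handled explicitly.
.G_DEGEN_X <- 1e-6

.conv3_kernel <- function(l, w, th, t, k = 1L) {
  x <- abs(w - th) * t
  degen <- x < .G_DEGEN_X
  out <- numeric(length(t))
  if (any(!degen)) {
    tt <- t[!degen]
    out[!degen] <- (.conv_kernel(l, th, tt, k) - .conv_kernel(l, w, tt, k)) / (w - th)
  }
  if (any(degen)) {
    tt <- t[degen]
    if (k == 1L) {
      # e^{-w.} * e^{-th.} -> t e^{-w t}; conv(e^{-l.}, (.)e^{-w.}) = F_2(w, l, .)
      out[degen] <- .conv_kernel(w, l, tt, k = 2L)
    } else {
      # conv((.)e^{-l.}, (.)e^{-w.}) = t F_2(l, w, t) - F_3(l, w, t)
      out[degen] <- tt * .conv_kernel(l, w, tt, k = 2L) - .conv_kernel(l, w, tt, k = 3L)
    }
  }
  out
}
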