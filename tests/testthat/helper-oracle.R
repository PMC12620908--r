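# Brute-force numerical-convolution oracle on a fine time grid (FFT with
# power-of-two padding and trapezoid end-correction). Test-only: the
# production path is fully analytic.
num_conv <- function(f, g, dt) {
  n <- length(f)
  N <- stats::nextn(2L * n, 2)
  out <- Re(stats::fft(stats::fft(c(f, rep(0, N - n))) *
                         stats::fft(c(g, rep(0, N - n))), inverse = TRUE))[1:n] / N
  out * dt - dt / 2 * (f[1] * g + g[1] * f)
}

# numerical reference curve and SRTM/FRTM predictions on a fine grid
oracle_curves <- function(p, kp, t_end = 93, dt = 0.001, frtm = FALSE) {
  tg <- seq(0, t_end, by = dt)
  fi <- feng_input(tg, p)
  cr <- num_conv(fi, p$g * exp(-p$w * tg), dt)
  if (is.null(kp)) return(list(tg = tg, cr = cr))
  if (!frtm) {
    ct <- kp$R1 * cr + (kp$k2 - kp$R1 * kp$k2a) * num_conv(cr, exp(-kp$k2a * tg), dt)
  } else {
    m <- simbaref:::.frtm_macro(kp)
    ct <- kp$R1 * (cr + num_conv(cr, m$A * exp(-m$al * tg) + m$B * exp(-m$be * tg), dt))
  }
  list(tg = tg, cr = cr, ct = ct)
}

grid_index <- function(tg, t) vapply(t, function(x) which.min(abs(tg - x)), integer(1))

random_ref_params <- function() {
  ref_curve_params(
    t0 = stats::runif(1, 0, 2), a1 = stats::runif(1, 20, 100),
    a2 = stats::runif(1, 1, 6), a3 = stats::runif(1, 0.3, 3),
    l1 = stats::runif(1, 2, 8), l2 = stats::runif(1, 0.2, 0.8),
    l3 = stats::runif(1, 0.005, 0.05),
    g = stats::runif(1, 0.1, 1), w = stats::runif(1, 0.02, 0.6))
}

random_kinetic_params <- function(k4 = NULL) {
  kinetic_params(R1 = stats::runif(1, 0.6, 1.3),
                 k2prime = stats::runif(1, 0.05, 0.25),
                 bpnd = stats::runif(1, 0.05, 4),
                 k4 = k4)
}

example_ref_params <- function() {
  ref_curve_params(0.5, 60, 3, 1, 4, 0.5, 0.02, 0.4, 0.12)
}
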