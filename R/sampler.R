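# No-U-Turn sampler (multinomial variant, dual-averaging step-size
# adaptation) over an arbitrary differentiable log posterior, written
# against the negative log posterior `fn` and its gradient `gr` as returned
# by TMB::MakeADFun. Two metrics are supported: an adaptively estimated
# diagonal metric (expanding warmup windows, Stan-style), and a fixed dense
# metric supplied as a covariance-structure Cholesky factor (typically the
# local curvature at a data-driven initialisation point), which removes the
# strong linear correlations of hierarchical mean decompositions.

# metric helpers ------------------------------------------------------------
.metric_diag <- function(minv) {
  list(type = "diag",
       minv = minv,
       sample_p = function(d) stats::rnorm(d) / sqrt(minv),
       minv_mult = function(p) minv * p)
}

# R upper-triangular with M = R'R (M = mass = local curvature)
.metric_dense <- function(R) {
  list(type = "dense",
       R = R,
       sample_p = function(d) drop(crossprod(R, stats::rnorm(d))),
       minv_mult = function(p) backsolve(R, backsolve(R, p, transpose = TRUE)))
}

.nuts_chain <- function(fn, gr, init, iter, warmup, seed,
                        max_treedepth = 10, target_accept = 0.8,
                        init_step = 0.1, divergence_gap = 1000,
                        metric = NULL, post_update = NULL,
                        metric_refresh = NULL) {
  set.seed(seed)
  d <- length(init)
  q <- init
  adapt_variance <- is.null(metric) || metric$type == "diag"
  if (is.null(metric)) metric <- .metric_diag(rep(1, d))
  eps <- init_step

  neg_logpost <- function(q) as.numeric(fn(q))
  grad_neg <- function(q) as.numeric(gr(q))

  # one leapfrog step carrying the gradient and the velocity v = M^-1 p so
  # each step costs one gradient, one objective and one metric solve
  step1 <- function(q, p, g, eps_s) {
    ph <- p - (eps_s / 2) * g
    q1 <- q + eps_s * metric$minv_mult(ph)
    g1 <- grad_neg(q1)
    p1 <- ph - (eps_s / 2) * g1
    v1 <- metric$minv_mult(p1)
    H <- neg_logpost(q1) + 0.5 * sum(p1 * v1)
    list(q = q1, p = p1, g = g1, v = v1, H = H)
  }

  # state tuples at the trajectory endpoints: (q, p, g, v)
  build <- function(st, dir, depth, H0) {
    if (depth == 0L) {
      s <- step1(st$q, st$p, st$g, dir * eps)
      H <- if (is.finite(s$H)) s$H else Inf
      div <- (H - H0) > divergence_gap
      node <- list(minus = s, plus = s, prop = s$q,
                   lw = H0 - H, sum_acc = min(1, exp(H0 - H)), n_acc = 1L,
                   diverged = div, ok = !div)
      node
    } else {
      left <- build(st, dir, depth - 1L, H0)
      if (!left$ok) return(left)
      right <- build(if (dir == 1L) left$plus else left$minus,
                     dir, depth - 1L, H0)
      out <- left
      out$sum_acc <- left$sum_acc + right$sum_acc
      out$n_acc <- left$n_acc + right$n_acc
      out$diverged <- left$diverged || right$diverged
      if (!right$ok) { out$ok <- FALSE; return(out) }
      if (dir == 1L) out$plus <- right$plus else out$minus <- right$minus
      lw_tot <- .logsumexp2(left$lw, right$lw)
      if (log(stats::runif(1)) < right$lw - lw_tot) out$prop <- right$prop
      out$lw <- lw_tot
      dq <- out$plus$q - out$minus$q
      out$ok <- sum(dq * out$minus$v) >= 0 && sum(dq * out$plus$v) >= 0
      out
    }
  }

  # crude bisection for a reasonable step size (acceptance near 0.5 after a
  # single leapfrog step); used at chain start and after metric changes
  find_eps <- function(q, g, u, eps0 = 1) {
    e <- eps0
    p <- metric$sample_p(d)
    v <- metric$minv_mult(p)
    H0 <- u + 0.5 * sum(p * v)
    dH_at <- function(e) {
      s <- step1(q, p, g, e)
      if (!is.finite(s$H)) Inf else s$H - H0
    }
    dh <- dH_at(e)
    dir <- if (is.finite(dh) && dh < log(2)) 1 else -1
    for (i in 1:30) {
      e2 <- e * if (dir > 0) 2 else 0.5
      dh2 <- dH_at(e2)
      if (dir > 0 && !(is.finite(dh2) && dh2 < log(2))) break
      if (dir < 0 && (is.finite(dh2) && dh2 < log(2))) { e <- e2; break }
      e <- e2
      if (e > 10 || e < 1e-7) break
    }
    min(max(e, 1e-7), 10)
  }

  da_reset <- function(eps0) {
    list(mu = log(10 * eps0), log_eps_bar = log(eps0), h_bar = 0, m = 0,
         gamma = 0.05, t0 = 10, kappa = 0.75)
  }
  da <- da_reset(eps)
  da_update <- function(da, accept_prob) {
    da$m <- da$m + 1
    eta <- 1 / (da$m + da$t0)
    da$h_bar <- (1 - eta) * da$h_bar + eta * (target_accept - accept_prob)
    log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
    w <- da$m^(-da$kappa)
    da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
    da$eps <- exp(log_eps)
    da
  }

  # expanding windows for diagonal-variance estimation
  w_init <- max(15L, floor(0.15 * warmup))
  w_term <- max(10L, floor(0.10 * warmup))
  win_ends <- integer(0)
  if (adapt_variance) {
    pos <- w_init
    len <- 25L
    while (pos + len < warmup - w_term) {
      pos <- pos + len
      win_ends <- c(win_ends, pos)
      len <- len * 2L
    }
    win_ends <- c(win_ends, warmup - w_term)
  }

  welford_n <- 0; welford_m <- numeric(d); welford_s <- numeric(d)
  draws <- matrix(NA_real_, iter - warmup, d)
  n_div <- 0L
  accept_sum <- 0
  treedepths <- integer(iter - warmup)

  g_cur <- grad_neg(q)
  u_cur <- neg_logpost(q)
  eps <- find_eps(q, g_cur, u_cur, eps)
  da <- da_reset(eps)
  for (it in seq_len(iter)) {
    p <- metric$sample_p(d)
    v <- metric$minv_mult(p)
    H0 <- u_cur + 0.5 * sum(p * v)
    if (!is.finite(H0)) stop("non-finite Hamiltonian at current state", call. = FALSE)
    st0 <- list(q = q, p = p, g = g_cur, v = v)
    tree <- list(minus = st0, plus = st0, prop = q, lw = 0,
                 ok = TRUE, diverged = FALSE)
    prop_changed <- FALSE
    depth <- 0L
    accept_stat <- 0; accept_n <- 0L
    while (tree$ok && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1L else 1L
      sub <- build(if (dir == 1L) tree$plus else tree$minus, dir, depth, H0)
      accept_stat <- accept_stat + sub$sum_acc
      accept_n <- accept_n + sub$n_acc
      if (sub$diverged) { n_div <- n_div + (it > warmup); tree$ok <- FALSE; break }
      if (!sub$ok) break
      if (dir == 1L) tree$plus <- sub$plus else tree$minus <- sub$minus
      lw_tot <- .logsumexp2(tree$lw, sub$lw)
      if (log(stats::runif(1)) < sub$lw - lw_tot) {
        tree$prop <- sub$prop
        prop_changed <- TRUE
      }
      tree$lw <- lw_tot
      dq <- tree$plus$q - tree$minus$q
      if (sum(dq * tree$minus$v) < 0 || sum(dq * tree$plus$v) < 0) {
        depth <- depth + 1L
        break
      }
      depth <- depth + 1L
    }
    q <- tree$prop
    if (!is.null(post_update)) {
      q <- post_update(q)
      prop_changed <- TRUE
    }
    if (prop_changed) {
      g_cur <- grad_neg(q)
      u_cur <- neg_logpost(q)
    }
    a_prob <- if (accept_n > 0) accept_stat / accept_n else 0

    if (it <= warmup) {
      da <- da_update(da, a_prob)
      eps <- da$eps
      if (!is.null(metric_refresh) && it == max(10L, floor(0.4 * warmup))) {
        # re-estimate the fixed metric at the current (typical-set) state,
        # where the local curvature is a better match than at the start
        new_metric <- metric_refresh(q)
        if (!is.null(new_metric)) {
          metric <- new_metric
          eps <- find_eps(q, g_cur, u_cur)
          da <- da_reset(eps)
        }
      }
      if (adapt_variance) {
        if (it > w_init && it <= warmup - w_term) {
          welford_n <- welford_n + 1
          delta <- q - welford_m
          welford_m <- welford_m + delta / welford_n
          welford_s <- welford_s + delta * (q - welford_m)
        }
        if (it %in% win_ends && welford_n > 4) {
          v <- welford_s / (welford_n - 1)
          minv <- (welford_n / (welford_n + 5)) * v + (5 / (welford_n + 5)) * 1e-3
          metric <- .metric_diag(minv)
          welford_n <- 0; welford_m <- numeric(d); welford_s <- numeric(d)
          eps <- find_eps(q, g_cur, u_cur)
          da <- da_reset(eps)
        }
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - warmup, ] <- q
      treedepths[it - warmup] <- depth
      accept_sum <- accept_sum + a_prob
    }
  }
  list(draws = draws, step_size = eps, n_divergent = n_div,
       mean_accept = accept_sum / (iter - warmup),
       mean_treedepth = mean(treedepths),
       metric_type = metric$type)
}

# univariate slice sampler (stepping out + shrinkage, Neal 2003); used for
# exact conditional updates of variance/correlation hyperparameters between
# NUTS iterations
.slice1 <- function(logp, x0, w = 0.5, m = 30L) {
  f0 <- logp(x0)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1)
  l <- x0 - w * stats::runif(1)
  r <- l + w
  j <- floor(m * stats::runif(1))
  k <- m - 1L - j
  while (j > 0 && is.finite(fl <- logp(l)) && y < fl) { l <- l - w; j <- j - 1L }
  while (k > 0 && is.finite(fr <- logp(r)) && y < fr) { r <- r + w; k <- k - 1L }
  for (try in 1:50) {
    x1 <- stats::runif(1, l, r)
    f1 <- logp(x1)
    if (is.finite(f1) && y <= f1) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
  x0
}

.logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Run NUTS chains over a TMB-style objective
#'
#' @param fn,gr Negative log posterior and its gradient (functions of the
#'   full parameter vector), e.g. `obj$fn`/`obj$gr` from [TMB::MakeADFun()].
#' @param init_fn Function of chain index returning an initial parameter
#'   vector.
#' @param n_par Parameter dimension.
#' @param chains,iter,warmup Chain count and per-chain iterations (warmup
#'   included in `iter`).
#' @param seed Master seed; chain c runs at `seed + c`.
#' @param metric `NULL` for an adaptively estimated diagonal metric, or a
#'   fixed metric from `.metric_dense()` / `.metric_diag()`.
#' @param ... Passed to the single-chain sampler (`max_treedepth`,
#'   `target_accept`, ...).
#' @return List with `draws` (array iter x chains x parameters) and
#'   per-chain sampler diagnostics.
#' @keywords internal
nuts_sample <- function(fn, gr, init_fn, n_par, chains = 3, iter = 1000,
                        warmup = floor(iter / 2), seed = 1,
                        metric = NULL, post_update = NULL,
                        metric_refresh = NULL, ...) {
  stopifnot(iter > warmup, chains >= 1)
  res <- lapply(seq_len(chains), function(cc) {
    .nuts_chain(fn, gr, init_fn(cc), iter = iter, warmup = warmup,
                seed = seed + cc, metric = metric, post_update = post_update,
                metric_refresh = metric_refresh, ...)
  })
  n_keep <- iter - warmup
  draws <- array(NA_real_, c(n_keep, chains, n_par))
  for (cc in seq_len(chains)) draws[, cc, ] <- res[[cc]]$draws
  list(draws = draws,
       diagnostics = lapply(res, function(r) r[setdiff(names(r), "draws")]))
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift registers as between-chain variance). Values
#' at or below 1.05 are taken as converged.
#'
#' @param x Matrix (iterations x chains) of draws for one scalar parameter.
#' @return The split-Rhat value.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size via chain-averaged autocorrelations with Geyer's
# initial-positive-sequence truncation.
.ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  acfs <- sapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = n - 2, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  })
  rho <- rowMeans(acfs)
  rho[!is.finite(rho)] <- 0
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(m * n)
  varplus <- W * (n - 1) / n + stats::var(colMeans(x))
  if (!is.finite(varplus) || varplus <= 0) return(m * n)
  rho_t <- 1 - (W - W * rho) / varplus
  rho_t[!is.finite(rho_t)] <- 0
  s <- 0; k <- 1
  while (k + 1 <= length(rho_t)) {
    pair <- rho_t[k] + rho_t[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- m * n / max(2 * s - 1, 1e-8)
  min(ess, m * n)
}
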