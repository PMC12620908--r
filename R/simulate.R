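#' Default population parameters for study simulation
#'
#' The generative settings emulate a serotonergic radiotracer study across
#' nine brain regions (anterior cingulate ACC, amygdala AMG, dorsal brain
#' stem DBS, frontal cortex FC, hippocampus HIP, insula INS, occipital
#' cortex OC, thalamus THA, ventral striatum VSTR), with regional mean BPND
#' spanning roughly 0.3-1.9 (DBS medium-to-low), modest regional variation
#' in delivery and reference clearance, and log-scale multivariate
#' subject- and TAC-level variation. Effect sizes follow the reference
#' simulation design: patients average 0.08 lower logBPND than healthy
#' volunteers, active treatment raises logBPND by 0.04 between sessions, and
#' placebo leaves it unchanged. Measurement error is generated from the same
#' log-linear sigma model the estimation side assumes (centred-log frame
#' duration / region volume / injected dose coefficients, a smooth profile
#' over scan time, and PET-to-PET and region-level deviations).
#'
#' All values are package defaults standing in for study-specific estimates
#' and are fully overridable.
#'
#' @param group_effect_logbpnd Patient-minus-HV shift on logBPND (default
#'   -0.08).
#' @param treatment_effect_logbpnd Post-minus-pre shift on logBPND in the
#'   active arm (default +0.04); the placebo effect is 0.
#' @return A `population_params` list.
#' @export
population_params <- function(group_effect_logbpnd = -0.08,
                              treatment_effect_logbpnd = 0.04) {
  regions <- c("ACC", "AMG", "DBS", "FC", "HIP", "INS", "OC", "THA", "VSTR")
  r1 <- c(0.95, 0.82, 0.80, 0.92, 0.78, 0.94, 1.00, 0.88, 0.85)
  bpnd <- c(1.10, 0.90, 0.45, 1.20, 0.70, 1.00, 1.90, 0.35, 1.40)
  k2p_dev <- c(0.06, 0.00, -0.02, 0.08, -0.10, 0.02, 0.00, -0.02, -0.02)
  volumes <- c(6, 3.5, 1.8, 50, 7, 12, 35, 15, 4)
  names(r1) <- names(bpnd) <- names(k2p_dev) <- names(volumes) <- regions

  alpha <- c(logR1 = mean(log(r1)), logk2prime = log(0.10),
             logBPND = mean(log(bpnd)))
  region_dev <- cbind(logR1 = log(r1) - alpha["logR1"],
                      logk2prime = k2p_dev,
                      logBPND = log(bpnd) - alpha["logBPND"])

  corr_subject <- matrix(c(1, 0.3, 0.5,
                           0.3, 1, 0.2,
                           0.5, 0.2, 1), 3, 3)
  sd_subject <- c(logR1 = 0.06, logk2prime = 0.08, logBPND = 0.20)
  corr_tac <- matrix(c(1, 0.3, 0.3,
                       0.3, 1, 0.3,
                       0.3, 0.3, 1), 3, 3)
  sd_tac <- c(logR1 = 0.025, logk2prime = 0.025, logBPND = 0.025)

  out <- list(
    regions = regions,
    region_volumes = volumes,
    reference_volume = 60,
    alpha = alpha,
    region_dev = region_dev,
    Sigma_subject = diag(sd_subject) %*% corr_subject %*% diag(sd_subject),
    Sigma_tac = diag(sd_tac) %*% corr_tac %*% diag(sd_tac),
    age_effect = c(logR1 = 0, logk2prime = -0.02, logBPND = -0.04),
    group_effect_logbpnd = group_effect_logbpnd,
    treatment_effect_logbpnd = treatment_effect_logbpnd,
    placebo_effect = 0,
    age_centre = 46,
    sigma = list(
      kappa0 = log(0.09),
      beta_dur = -0.5,
      beta_vol = -0.5,
      beta_dose = -0.3,
      smooth = function(t) 0.0035 * t - 0.35 * exp(-t / 4),
      sd_meas = 0.2,
      sd_region = 0.1,
      centre_dur = log(2),     # minutes; centring constants of the
      centre_vol = log(9),     # generative model (natural-log scale)
      centre_dose = log(350)
    ),
    dose_mean = 350, dose_sd = 25,
    age_range = c(22, 70)
  )
  .check_psd(out$Sigma_subject, "Sigma_subject")
  .check_psd(out$Sigma_tac, "Sigma_tac")
  class(out) <- "population_params"
  out
}

#' Restrict population parameters to a subset of regions
#'
#' Convenience for reduced-scale simulations: keeps the named regions'
#' fixed deviations and volumes; all other settings are unchanged.
#'
#' @param pop A [population_params()] object.
#' @param keep Character vector of region names to retain.
#' @return A `population_params` object over the subset.
#' @export
subset_regions <- function(pop, keep) {
  stopifnot(inherits(pop, "population_params"), all(keep %in% pop$regions))
  pop$regions <- keep
  pop$region_volumes <- pop$region_volumes[keep]
  pop$region_dev <- pop$region_dev[keep, , drop = FALSE]
  pop
}

.check_psd <- function(S, name) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) {
    stop(sprintf("`%s` must be positive-semidefinite", name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Shipped synthetic reference-curve shapes
#'
#' Five synthetic Feng-1TC parameter sets spanning realistic reference-TAC
#' shapes (peak 2.5-6 kBq/mL between 3 and 8 minutes, slow tail decline),
#' used to seed the simulated reference-curve library when no fitted curves
#' are available. These are synthetic stand-ins, not fits to any measured
#' data.
#'
#' @return List of five [ref_curve_params()].
#' @export
base_ref_params <- function() {
  list(
    ref_curve_params(0.50, 60, 3.0, 1.0, 4.0, 0.50, 0.020, 0.40, 0.120),
    ref_curve_params(0.80, 90, 5.0, 1.5, 5.0, 0.40, 0.015, 0.50, 0.100),
    ref_curve_params(0.30, 45, 2.5, 0.8, 3.0, 0.60, 0.030, 0.60, 0.180),
    ref_curve_params(1.00, 75, 4.0, 1.2, 6.0, 0.35, 0.010, 0.35, 0.080),
    ref_curve_params(0.60, 55, 3.5, 1.0, 3.5, 0.55, 0.025, 0.50, 0.150)
  )
}

# generative per-frame log-sigma profile (duration + smooth over time),
# relative to the global mean level
.sigma_frame_profile <- function(frames, sig) {
  sig$beta_dur * (log(frames$frame_duration) - sig$centre_dur) +
    sig$smooth(frames$frame_mid)
}

.sigma_level <- function(sig, volume, dose) {
  sig$kappa0 + sig$beta_vol * (log(volume) - sig$centre_vol) +
    sig$beta_dose * (log(dose) - sig$centre_dose)
}

#' Add frame-level measurement noise to a noise-free curve
#'
#' Implements the five-step noise construction: (1) a per-frame logsigma
#' profile (frame-duration coefficient plus a smooth function over scan
#' time), (2) a mean logsigma level, (3) a PET-to-PET measurement deviation
#' drawn from Normal(0, sd_meas) on the log scale, (4) all components summed
#' in logsigma, and (5) independent normal noise with the resulting sigma
#' added to each time point.
#'
#' @param true_curve Noise-free activities per frame.
#' @param sigma_components List with `logsigma_mean` (scalar),
#'   `logsigma_frame` (per-frame vector) and `sd_meas` (log-scale SD of the
#'   measurement-level deviation); an explicit `meas_dev` overrides the
#'   random draw.
#' @param seed Integer seed.
#' @return List with `curve` (noisy activities), `sigma` (per-frame SD used)
#'   and `meas_dev` (the measurement-level logsigma deviation).
#' @export
simulate_frame_noise <- function(true_curve, sigma_components, seed) {
  sc <- sigma_components
  withr_seed(seed, {
    meas_dev <- if (!is.null(sc$meas_dev)) sc$meas_dev else {
      stats::rnorm(1, 0, sc$sd_meas)
    }
    sigma <- exp(sc$logsigma_mean + sc$logsigma_frame + meas_dev)
    list(curve = true_curve + stats::rnorm(length(true_curve), 0, sigma),
         sigma = sigma, meas_dev = meas_dev)
  })
}

#' Build a simulated reference-TAC library
#'
#' Samples base Feng-1TC parameter sets with replacement to generate *true*
#' reference curves, adds realistic frame-level noise to produce *measured*
#' curves, and refits each measured curve by multi-start bounded least
#' squares to obtain *estimated* parameters. Each entry therefore carries
#' the four elements needed to keep simulation truth and downstream fitting
#' strictly separated.
#'
#' @param base_fits List of [ref_curve_params()] (or `ref_fit` objects);
#'   defaults to the shipped synthetic shapes [base_ref_params()].
#' @param n Library size (default 500).
#' @param frames [frame_schedule()] for the library curves.
#' @param pop [population_params()] supplying the noise model.
#' @param noise_scale Multiplier on the generative sigma (0 gives noise-free
#'   "measured" curves).
#' @param n_starts Multi-start count for the refits.
#' @param seed Master seed.
#' @param max_retries Refit attempts (fresh noise) per entry before the
#'   entry is flagged.
#' @return A `ref_library`: list of entries with `true_params`, `true_curve`,
#'   `measured_curve`, `estimated_params`, `sigma`, `qc_flags`.
#' @export
build_reference_library <- function(base_fits = base_ref_params(), n = 500,
                                    frames = default_frame_schedule(),
                                    pop = population_params(),
                                    noise_scale = 1, n_starts = 20, seed = 1,
                                    max_retries = 3) {
  stopifnot(length(base_fits) >= 1, n >= 1)
  frames <- .assert_frame_schedule(frames)
  base_params <- lapply(base_fits, function(b) {
    if (inherits(b, "ref_fit")) b$params else b
  })
  sig <- pop$sigma
  logsigma_frame <- .sigma_frame_profile(frames, sig)
  logsigma_mean <- .sigma_level(sig, pop$reference_volume, pop$dose_mean) +
    log(max(noise_scale, 1e-12))
  entries <- withr_seed(seed, {
    idx <- sample.int(length(base_params), n, replace = TRUE)
    sub_seeds <- sample.int(.Machine$integer.max - 10L, n * (max_retries + 1))
    lapply(seq_len(n), function(i) list(base = idx[i],
                                        seeds = sub_seeds[seq.int(i, by = n,
                                                                  length.out = max_retries + 1)]))
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tp <- base_params[[entries[[i]]$base]]
    true_curve <- ref_curve(frames$frame_mid, tp)
    entry <- NULL
    last <- NULL
    for (r in seq_len(max_retries + 1)) {
      nz <- simulate_frame_noise(
        true_curve,
        list(logsigma_mean = logsigma_mean,
             logsigma_frame = logsigma_frame, sd_meas = sig$sd_meas),
        seed = entries[[i]]$seeds[r])
      # retries stand in for visual inspection of poor fits: fresh noise and
      # a denser multi-start sweep each round
      fit <- fit_reference(nz$curve, frames, n_starts = n_starts * r,
                           seed = entries[[i]]$seeds[r])
      if (!fit$converged) next
      fit <- qc_reference(fit, nz$curve)
      last <- list(true_params = tp, true_curve = true_curve,
                   measured_curve = nz$curve,
                   estimated_params = fit$params, sigma = nz$sigma,
                   qc_flags = fit$qc_flags, retries = r - 1L)
      if (length(fit$qc_flags) == 0) {
        entry <- last
        break
      }
    }
    if (is.null(entry)) {
      # still flagged after every retry: kept for inspection, but its
      # estimated parameters are withheld so downstream fitting never
      # conditions on a visibly poor reference fit
      entry <- list(true_params = tp, true_curve = true_curve,
                    measured_curve = if (is.null(last)) NULL else last$measured_curve,
                    estimated_params = NULL, sigma = NULL,
                    qc_flags = if (is.null(last)) "fit_failure" else
                      c("underfit", last$qc_flags),
                    retries = max_retries)
    }
    out[[i]] <- entry
  }
  structure(list(entries = out, frames = frames, seed = seed),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  flagged <- sum(vapply(x$entries, function(e) length(e$qc_flags) > 0, logical(1)))
  cat(sprintf("<ref_library: %d entries (%d QC-flagged), %d frames>\n",
              length(x$entries), flagged, nrow(x$frames)))
  invisible(x)
}

#' Simulate true PK parameters for one subject
#'
#' Draws log-scale parameters for every region and session of a subject:
#' population intercepts plus fixed regional deviations, covariate effects
#' (age per centred decade; the -0.08 patient shift on logBPND; the +0.04
#' active-treatment shift for post sessions, 0 under placebo), one
#' subject-level MVN draw shared across the subject's sessions, and an
#' independent TAC-level MVN draw per session x region.
#'
#' @param pop [population_params()].
#' @param subject List or one-row data frame with `group` ("HV"/"MDD"),
#'   `arm` ("placebo"/"active") and `age` (years).
#' @param sessions Character vector of session labels; the first is the
#'   pre/baseline session.
#' @param seed Integer seed.
#' @return Tibble with one row per session x region: log-scale and
#'   natural-scale true parameters.
#' @export
simulate_subject_params <- function(pop, subject, sessions = c("pre", "post"),
                                    seed = 1) {
  stopifnot(inherits(pop, "population_params"))
  regions <- pop$regions
  age_c <- (subject$age - pop$age_centre) / 10
  is_pat <- subject$group != "HV"
  is_active <- subject$arm == "active"
  withr_seed(seed, {
    tau <- drop(.mvn_draw(1, pop$Sigma_subject))
    rows <- list()
    for (s in seq_along(sessions)) {
      post <- as.numeric(s > 1)
      eff_treat <- if (is_active) post * pop$treatment_effect_logbpnd else
        post * pop$placebo_effect
      phi <- .mvn_draw(length(regions), pop$Sigma_tac)
      th <- sapply(1:3, function(i) {
        pop$alpha[i] + pop$region_dev[regions, i] + pop$age_effect[i] * age_c +
          tau[i] + phi[, i]
      })
      dimnames(th) <- NULL
      th[, 3] <- th[, 3] + is_pat * pop$group_effect_logbpnd + eff_treat
      rows[[s]] <- tibble::tibble(
        session = sessions[s], region = regions,
        logR1 = th[, 1], logk2prime = th[, 2], logBPND = th[, 3],
        R1 = exp(th[, 1]), k2prime = exp(th[, 2]), bpnd = exp(th[, 3]))
    }
    dplyr::bind_rows(rows)
  })
}

.mvn_draw <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(ev$values < -1e-10)) stop("covariance must be PSD", call. = FALSE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(A)
}

#' Construct a two-group pre/post study design
#'
#' Healthy volunteers receive placebo, patients receive active treatment
#' (the reference simulation design).
#'
#' @param n_hv,n_patient Subjects per group.
#' @param sessions Session labels (first = baseline); use a single label for
#'   cross-sectional designs.
#' @return Tibble with one row per subject: subject, group, arm.
#' @export
study_design <- function(n_hv = 10, n_patient = 10,
                         sessions = c("pre", "post")) {
  design <- tibble::tibble(
    subject = sprintf("s%02d", seq_len(n_hv + n_patient)),
    group = rep(c("HV", "MDD"), c(n_hv, n_patient)),
    arm = rep(c("placebo", "active"), c(n_hv, n_patient)))
  attr(design, "sessions") <- sessions
  design
}

#' Simulate a complete TAC study
#'
#' Generates, from a master seed, a full synthetic study: ages and injected
#' doses, true per-TAC kinetic parameters (via
#' [simulate_subject_params()]), target curves computed through the
#' analytic SRTM forward model using the *true* Feng-1TC parameters of a
#' reference-library entry assigned to each measurement, and frame-level
#' noise from the generative sigma model. The returned bundle records the
#' *estimated* reference parameters separately so that downstream model
#' fitting never touches the simulation truth (and vice versa).
#'
#' @param pop [population_params()].
#' @param design A [study_design()] tibble.
#' @param library A `ref_library` from [build_reference_library()].
#' @param frames [frame_schedule()] for the target TACs (defaults to the
#'   library's).
#' @param seed Master seed; regeneration from (design, seed) is
#'   bit-identical.
#' @return A `sim_study` object.
#' @export
simulate_dataset <- function(pop, design, library,
                             frames = library$frames, seed = 1) {
  stopifnot(inherits(pop, "population_params"),
            inherits(library, "ref_library"))
  frames <- .assert_frame_schedule(frames)
  sessions <- attr(design, "sessions") %||% "baseline"
  ok_entries <- which(vapply(library$entries,
                             function(e) !is.null(e$estimated_params), logical(1)))
  if (!length(ok_entries)) stop("reference library has no usable entries", call. = FALSE)
  regions <- pop$regions
  nslib <- length(ok_entries)

  withr_seed(seed, {
    ns <- nrow(design)
    ages <- round(stats::runif(ns, pop$age_range[1], pop$age_range[2]), 1)
    subj_seeds <- sample.int(.Machine$integer.max - 10L, ns)
    meas <- tidyr::expand_grid(subject = design$subject, session = sessions)
    meas <- dplyr::left_join(meas, design, by = "subject")
    nm <- nrow(meas)
    meas$meas_id <- sprintf("%s_%s", meas$subject, meas$session)
    meas$age <- ages[match(meas$subject, design$subject)]
    meas$dose <- round(stats::rnorm(nm, pop$dose_mean, pop$dose_sd), 1)
    meas$centre <- "SIM"
    meas$lib_idx <- ok_entries[sample.int(nslib, nm, replace = TRUE)]
    meas$logsig_meas <- stats::rnorm(nm, 0, pop$sigma$sd_meas)
    region_sig_dev <- stats::rnorm(length(regions), 0, pop$sigma$sd_region)
    names(region_sig_dev) <- regions
    noise_seeds <- sample.int(.Machine$integer.max - 1000L, nm)

    truth <- vector("list", ns)
    for (j in seq_len(ns)) {
      truth[[j]] <- simulate_subject_params(
        pop,
        list(group = design$group[j], arm = design$arm[j], age = ages[j]),
        sessions = sessions, seed = subj_seeds[j])
      truth[[j]]$subject <- design$subject[j]
    }
    truth <- dplyr::bind_rows(truth)

    lsf <- .sigma_frame_profile(frames, pop$sigma)
    tac_rows <- vector("list", nm)
    for (m in seq_len(nm)) {
      ent <- library$entries[[meas$lib_idx[m]]]
      tr <- truth[truth$subject == meas$subject[m] &
                    truth$session == meas$session[m], ]
      tr <- tr[match(regions, tr$region), ]
      ys <- matrix(NA_real_, nrow(frames), length(regions))
      sink_seed <- noise_seeds[m]
      for (k in seq_along(regions)) {
        kp <- kinetic_params(tr$R1[k], tr$k2prime[k], tr$bpnd[k])
        mu <- srtm_predict(frames, kp, ent$true_params)
        lvl <- .sigma_level(pop$sigma, pop$region_volumes[regions[k]],
                            meas$dose[m]) +
          region_sig_dev[regions[k]] + meas$logsig_meas[m]
        sigma <- exp(lvl + lsf)
        ys[, k] <- mu + withr_seed(sink_seed + k,
                                   stats::rnorm(nrow(frames), 0, sigma))
      }
      colnames(ys) <- regions
      tac_rows[[m]] <- list(meas_id = meas$meas_id[m], tacs = ys,
                            ref = ent$measured_curve)
    }

    out <- list(design = design, meta = meas, truth = truth,
                frames = frames, regions = regions,
                region_volumes = pop$region_volumes,
                reference_volume = pop$reference_volume,
                tac_rows = tac_rows, pop = pop,
                library_seed = library$seed, seed = seed,
                ref_source_simulation = "true_params",
                ref_source_fitting = "estimated_params",
                library = library)
    class(out) <- "sim_study"
    out
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study: %d subjects, %d measurements, %d regions, seed %d>\n",
              nrow(x$design), nrow(x$meta), length(x$regions), x$seed))
  invisible(x)
}

#' Convert a simulated study to a modelling dataset
#'
#' Uses the *estimated* Feng-1TC parameters of each measurement's library
#' entry (the true parameters are reserved for data generation; requesting
#' them is possible for oracle analyses but is clearly marked).
#'
#' @param study A `sim_study`.
#' @param ref `"estimated"` (default) or `"true"`.
#' @return A `simba_data` object with an `audit` attribute recording the
#'   reference-parameter source.
#' @export
as_simba_data <- function(study, ref = c("estimated", "true")) {
  stopifnot(inherits(study, "sim_study"))
  ref <- match.arg(ref)
  tables <- lapply(seq_len(nrow(study$meta)), function(m) {
    mm <- study$meta[m, ]
    structure(list(
      frames = study$frames,
      tacs = study$tac_rows[[m]]$tacs,
      ref = study$tac_rows[[m]]$ref,
      meta = list(meas_id = mm$meas_id, subject = mm$subject,
                  group = mm$group, centre = mm$centre, session = mm$session,
                  arm = mm$arm, age = mm$age, dose = mm$dose,
                  region_volumes = as.list(study$region_volumes))),
      class = "tac_table")
  })
  ref_params <- lapply(study$meta$lib_idx, function(i) {
    e <- study$library$entries[[i]]
    if (ref == "estimated") e$estimated_params else e$true_params
  })
  out <- simba_data(tables, ref_params)
  attr(out, "audit") <- list(ref_source = ref)
  out
}

#' True parameter table of a simulated study
#'
#' @param study A `sim_study`.
#' @return Tibble keyed by meas_id and region with true natural-scale
#'   parameters.
#' @export
sim_truth <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  tr <- dplyr::left_join(study$truth,
                         dplyr::select(study$meta, "meas_id", "subject",
                                       "session", "group", "arm"),
                         by = c("subject", "session"))
  dplyr::select(tr, "meas_id", "subject", "session", "group", "arm",
                "region", "logR1", "logk2prime", "logBPND",
                "R1", "k2prime", "bpnd")
}
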