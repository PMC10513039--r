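# Synthetic multi-subject cohort generator: time-aligned PPG, continuous
# BP and per-beat stroke volume at 100 Hz with known ground-truth
# hemodynamics, emulating the shape of the 40-subject supine reference
# recordings (~5 min per subject, Finometer BP/SV + finger PPG).

#' Cohort specification
#'
#' Defaults state the emulated world: 40 subjects, 300 s at 100 Hz;
#' hemodynamics drawn from the sweep-protocol ranges (R 0.7--1.3 mmHg s/mL,
#' CO 4.25--5.95 L/min, cardiac period 0.7--1.0 s, compliance profiles from
#' the bundled 45-profile set); per-beat CO/R stimuli are AR(1) sequences
#' with marginal SD `noise_halfwidth/sqrt(3)` (the white-noise protocol is
#' `phi = 0`); measurement noise is white, 1% of the PPG pulse amplitude;
#' per-subject sensor gain is uniform on 0.8--1.2.
#'
#' `info_inject` is test scaffolding, off by default: it adds a slow
#' within-recording drift of R (raising MAP variation, hence CO-fluctuation
#' information carried by temporal features) together with a slow PPG gain
#' wander that corrupts amplitude-based morphology but leaves
#' scale-invariant temporal features untouched.
#'
#' @param n_subjects number of subjects, default 40.
#' @param duration recording length (s), default 300.
#' @param fs sampling rate (Hz), default 100.
#' @param r_range,co_range,t_range hemodynamic sampling ranges
#'   (mmHg s/mL, L/min, s).
#' @param profiles candidate compliance profiles
#'   (default [langewouters_profiles()]).
#' @param phi_sv,phi_r AR(1) coefficients of the per-beat CO and R stimuli,
#'   default 0.3 (mild autocorrelation; 0 = white).
#' @param noise_halfwidth stimulus half-width (fraction), default 0.05.
#' @param meas_noise_sd measurement noise as a fraction of the median PPG
#'   pulse amplitude, default 0.01.
#' @param gain_range per-subject PPG gain range, default c(0.8, 1.2).
#' @param info_inject logical, see above.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40, duration = 300, fs = 100,
                        r_range = c(0.7, 1.3), co_range = c(4.25, 5.95),
                        t_range = c(0.7, 1.0),
                        profiles = langewouters_profiles(),
                        phi_sv = 0.3, phi_r = 0.3,
                        noise_halfwidth = 0.05, meas_noise_sd = 0.01,
                        gain_range = c(0.8, 1.2), info_inject = FALSE,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, duration > 0, fs > 0,
            phi_sv >= 0, phi_sv < 1, phi_r >= 0, phi_r < 1,
            noise_halfwidth >= 0, meas_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Stationary AR(1) multiplicative perturbation series
#'
#' Zero-mean AR(1) with innovations scaled so the marginal SD equals
#' `halfwidth / sqrt(3)` (matching the uniform white-noise protocol's SD),
#' clipped to +/- 3 SD.  `phi = 0` gives i.i.d. draws.
#'
#' @param n length.
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param halfwidth nominal half-width (fraction of baseline), default 0.05.
#' @param seed optional seed (uses and advances the current RNG stream when
#'   `NULL`).
#' @return numeric vector of fractional perturbations.
#' @export
ar1_series <- function(n, phi, halfwidth = 0.05, seed = NULL) {
  stopifnot(phi >= 0, phi < 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  marg_sd <- halfwidth / sqrt(3)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, marg_sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, marg_sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  pmin(pmax(x, -3 * marg_sd), 3 * marg_sd)
}

# simulate one subject; returns list(recording=data.frame, truth=list)
simulate_subject <- function(spec, subject_id, profile_row, R0, CO0, T) {
  n_beats <- ceiling(spec$duration / T) + 1L
  # info injection draws heterogeneous per-subject stimulus levels so the
  # pooled CO-fluctuation split separates genuinely calm and unstable
  # subjects rather than realization noise
  hw <- spec$noise_halfwidth * if (spec$info_inject) runif(1, 0.4, 1.6) else 1
  co_pert <- ar1_series(n_beats, spec$phi_sv, hw)
  r_pert <- ar1_series(n_beats, spec$phi_r, hw)
  # info injection: a slow R drift whose amplitude scales with the
  # subject's CO-stimulus fluctuation level, so per-epoch BP drift (and the
  # temporal-feature information that tracks it) is largest exactly where
  # CO fluctuates most
  r_drift <- if (spec$info_inject) {
    fluct_level <- mean(abs(diff(co_pert))) /
      (spec$noise_halfwidth / sqrt(3) + 1e-12)
    amp <- 0.15 * min(1.5, 0.4 + 0.6 * fluct_level)
    amp * sin(2 * pi * seq_len(n_beats) * T / 100 + runif(1, 0, 2 * pi))
  } else 0
  co_beats <- CO0 * (1 + co_pert)
  r_beats <- R0 * (1 + r_pert) * (1 + r_drift)
  profile <- profile_from_row(profile_row)
  Ts <- min(0.35, 0.5 * T)
  inflow <- lapply(co_beats, function(co)
    cardiac_inflow(q0_from_co(co, T, Ts), T, Ts))
  sys <- windkessel_system(profile, C2 = 0.1, R = r_beats, L = 0.03,
                           inflow = inflow)
  gain <- runif(1, spec$gain_range[1], spec$gain_range[2])
  transfer <- pv_spec_from_profile(profile, gain = gain)
  sim <- simulate_wk4(sys, dt = 1 / spec$fs, transfer = transfer)
  n <- length(sim$p_p$values)
  ppg <- sim$ppg$values
  if (spec$info_inject) {
    # slow sensor-coupling wander (multiplicative gain drift): corrupts
    # amplitude-based morphology (AC and DC), while scale-invariant
    # temporal features are nearly untouched
    tfull <- (seq_len(n) - 1) / spec$fs
    wander <- 1 + 0.3 * sin(2 * pi * tfull / 75 + runif(1, 0, 2 * pi))
    ppg <- ppg * wander
  }
  bs <- sim$beat_starts
  ac_med <- median(vapply(seq_along(bs), function(i) {
    j <- if (i < length(bs)) bs[i + 1] - 1L else n
    max(ppg[bs[i]:j]) - min(ppg[bs[i]:j])
  }, numeric(1)))
  if (spec$meas_noise_sd > 0)
    ppg <- ppg + rnorm(n, 0, spec$meas_noise_sd * ac_med)
  # per-beat SV as a step channel on the grid
  sv_beats <- vapply(sys$inflow, stroke_volume, numeric(1))
  sv_grid <- sv_beats[findInterval(seq_len(n), bs)]
  keep <- seq_len(min(n, round(spec$duration * spec$fs)))
  rec <- data.frame(time_s = (keep - 1) / spec$fs,
                    ppg = ppg[keep], bp = sim$p_p$values[keep],
                    sv = sv_grid[keep])
  truth <- data.frame(subject_id = subject_id,
                      profile_id = profile_row$profile_id,
                      Am = profile_row$Am, P0 = profile_row$P0,
                      P1 = profile_row$P1, l = profile_row$l,
                      R = R0, CO = CO0, T = T, Ts = Ts, C2 = 0.1, L = 0.03,
                      gain = gain,
                      map_sim = mean(sim$p_p$values[keep]),
                      sbp_ok = sim$sbp_ok)
  list(recording = rec, truth = truth,
       beats = data.frame(subject_id = subject_id,
                          beat = seq_along(co_beats),
                          co = co_beats, r = r_beats * 1))
}

#' Generate a synthetic cohort
#'
#' Per subject: hemodynamics are drawn uniformly from the spec ranges (the
#' compliance profile from the bundled 45-profile set), per-beat CO/R
#' follow AR(1) stimulus sequences, the Windkessel model is simulated, and
#' PPG is produced by a personalized pressure-volume transfer with
#' per-subject gain plus white measurement noise.  A subject whose systolic
#' pressure leaves the 80--220 mmHg band is resampled (max 3 retries,
#' logged via message).
#'
#' @param spec a [cohort_spec()].
#' @return list of class `wkppg_cohort`: `recordings` (named list of
#'   data.frames `time_s, ppg, bp, sv`), `truth` (one row per subject),
#'   `beats` (per-beat ground-truth CO/R), `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  recs <- list()
  truth <- list()
  beats <- list()
  for (s in seq_len(spec$n_subjects)) {
    id <- sprintf("S%03d", s)
    res <- NULL
    failures <- 0L
    for (draw in 1:50) {
      prow <- spec$profiles[sample.int(nrow(spec$profiles), 1), ]
      R0 <- runif(1, spec$r_range[1], spec$r_range[2])
      CO0 <- runif(1, spec$co_range[1], spec$co_range[2])
      T <- runif(1, spec$t_range[1], spec$t_range[2])
      cand <- tryCatch(simulate_subject(spec, id, prow, R0, CO0, T),
                       error = function(e) {
                         failures <<- failures + 1L
                         message(sprintf("subject %s: simulation failed (%s)",
                                         id, conditionMessage(e)))
                         NULL
                       })
      if (failures > 3)
        stop("simulation failed repeatedly for subject ", id)
      if (!is.null(cand) && cand$truth$sbp_ok) {
        res <- cand
        break
      }
      # healthy-cohort rejection sampling: SBP must stay in 80-220 mmHg
      if (!is.null(cand))
        message(sprintf("subject %s draw %d out of SBP range; resampling",
                        id, draw))
    }
    if (is.null(res))
      stop("could not generate an in-range subject for ", id)
    recs[[id]] <- res$recording
    truth[[id]] <- res$truth
    beats[[id]] <- res$beats
  }
  structure(list(recordings = recs, truth = do.call(rbind, truth),
                 beats = do.call(rbind, beats), spec = spec),
            class = "wkppg_cohort")
}

#' @export
print.wkppg_cohort <- function(x, ...) {
  cat(sprintf("<wkppg_cohort> %d subjects x %g s @ %g Hz\n",
              length(x$recordings), x$spec$duration, x$spec$fs))
  invisible(x)
}

#' Rescale the PPG channel of a recording
#'
#' Mimics a changed sensor-skin coupling: only the PPG channel is
#' multiplied by `factor`; BP and SV are untouched.
#'
#' @param recording data.frame with a `ppg` column (as produced by
#'   [make_cohort()]), or a `recording` object.
#' @param factor positive scale factor.
#' @return The recording with `ppg` scaled.
#' @export
scale_ppg <- function(recording, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  if (inherits(recording, "recording")) {
    recording$ppg$values <- recording$ppg$values * factor
  } else {
    stopifnot("ppg" %in% names(recording))
    recording$ppg <- recording$ppg * factor
  }
  recording
}

#' Write a cohort to disk
#'
#' One CSV per subject plus `ground_truth.csv` and a `manifest.json`
#' recording the seed and a hash of the spec.
#'
#' @param cohort a `wkppg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wkppg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(cohort$recordings))
    write.csv(cohort$recordings[[id]], file.path(dir, paste0(id, ".csv")),
              row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  spec_plain <- cohort$spec
  spec_plain$profiles <- NULL
  manifest <- list(seed = cohort$spec$seed,
                   n_subjects = cohort$spec$n_subjects,
                   spec_hash = sum(utf8ToInt(paste(
                     vapply(spec_plain[order(names(spec_plain))],
                            function(v) paste(format(v), collapse = ","),
                            character(1)), collapse = ";"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
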