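#' The bundled central compliance profiles
#'
#' Returns the 45 Langewouters-style arctangent profiles used by the sweep
#' protocols.  The first two are the published exemplars
#' (Aorta1: Am = 3.5 cm^2, P0 = 50.4 mmHg, P1 = 42.3 mmHg;
#' Aorta2: Am = 6.18 cm^2, P0 = -2.3 mmHg, P1 = 21.6 mmHg); the remaining 43
#' are a fixed, internally seeded parametric sample covering
#' Am in \[3, 7\] cm^2, P0 in \[-10, 60\] mmHg, P1 in \[15, 45\] mmHg.
#' They are a synthetic stand-in for the published table, which is not
#' reproduced here; the sample is byte-identical across calls and does not
#' disturb the caller's RNG state.
#'
#' All profiles carry `l = 100` cm, the package's effective arterial-tree
#' length (see the methods vignette): it scales the unit-length Langewouters
#' compliance to a physiological whole-tree central compliance.
#'
#' @param n number of profiles (default 45, the protocol size).
#' @param l unit length attached to every profile (cm), default 100.
#' @return A data.frame with columns `profile_id`, `Am`, `P0`, `P1`, `l`.
#' @export
langewouters_profiles <- function(n = 45, l = 100) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(193707L)  # fixed: the profile set is part of the stated protocol
  m <- n - 2
  df <- data.frame(
    profile_id = seq_len(n),
    Am = c(3.5, 6.18, runif(m, 3, 7)),
    P0 = c(50.4, -2.3, runif(m, -10, 60)),
    P1 = c(42.3, 21.6, runif(m, 15, 45)),
    l = l)
  df
}

# row of the profile table -> compliance_profile
profile_from_row <- function(row) {
  compliance_profile(row$Am, row$P0, row$P1, row$l)
}

#' Pulse stimulus specification
#'
#' `kind = "sv"`: a fractional increase of one beat's peak flow q0 (default
#' +20%) lasting exactly one cardiac cycle; `onset` is the beat index.
#' `kind = "mini"`: a fractional increase of the instantaneous inflow
#' (default +10%) lasting 0.01 s; `onset` is a time in seconds (default
#' `NULL` = the peak-ejection time of the first beat, where the response is
#' maximal).
#'
#' @param kind `"sv"` or `"mini"`.
#' @param magnitude fractional increase (> -1); defaults 0.20 (sv), 0.10 (mini).
#' @param onset beat index (sv) or time in s (mini).
#' @param duration stimulus duration (s); defaults to one cycle (sv) or 0.01 s.
#' @return An object of class `pulse_stimulus`.
#' @export
pulse_stimulus <- function(kind = c("sv", "mini"), magnitude = NULL,
                           onset = NULL, duration = NULL) {
  kind <- match.arg(kind)
  if (is.null(magnitude)) magnitude <- if (kind == "sv") 0.20 else 0.10
  if (magnitude <= -1) stop("magnitude must be > -1")
  if (is.null(duration)) duration <- if (kind == "mini") 0.01 else NA_real_
  structure(list(kind = kind, magnitude = magnitude, onset = onset,
                 duration = duration), class = "pulse_stimulus")
}

#' Apply a stroke-volume pulse stimulus
#'
#' Multiplies q0 of exactly one beat by `1 + magnitude`; all other beats are
#' untouched.  The system's inflow sequence is expanded to `n_beats` first,
#' so baseline and perturbed runs share an identical beat grid.
#'
#' @param system a [windkessel_system()].
#' @param stimulus a [pulse_stimulus()] of kind `"sv"` (onset = beat index,
#'   default the middle beat).
#' @param n_beats number of beats of the run (default: inflow length).
#' @return The perturbed `windkessel_system`.
#' @export
make_sv_pulse <- function(system, stimulus = pulse_stimulus("sv"),
                          n_beats = NULL) {
  stopifnot(inherits(system, "windkessel_system"),
            inherits(stimulus, "pulse_stimulus"), stimulus$kind == "sv")
  inflow <- expand_inflow(system, n_beats)
  onset <- stimulus$onset
  if (is.null(onset)) onset <- ceiling(length(inflow) / 2)
  if (onset < 1 || onset > length(inflow))
    stop("onset beat out of range")
  b <- inflow[[onset]]
  inflow[[onset]] <- cardiac_inflow(b$q0 * (1 + stimulus$magnitude),
                                    b$T, b$Ts, b$alpha)
  out <- system
  out$inflow <- inflow
  if (length(out$R) == 1) out$R <- rep(out$R, length(inflow))
  out
}

#' Apply a "mini" inflow pulse stimulus
#'
#' Multiplies the instantaneous inflow by `1 + magnitude` over one short
#' window (default 0.01 s).  Onset is a time in seconds on the post-warm-up
#' timeline; the default is the peak-ejection instant of the middle beat.
#' A stimulus placed in diastole (where q_in = 0) carries no energy and
#' triggers a warning.
#'
#' @inheritParams make_sv_pulse
#' @param stimulus a [pulse_stimulus()] of kind `"mini"`.
#' @return The perturbed `windkessel_system` (with a modifier window).
#' @export
make_mini_pulse <- function(system, stimulus = pulse_stimulus("mini"),
                            n_beats = NULL) {
  stopifnot(inherits(system, "windkessel_system"),
            inherits(stimulus, "pulse_stimulus"), stimulus$kind == "mini")
  inflow <- expand_inflow(system, n_beats)
  Tvec <- vapply(inflow, `[[`, numeric(1), "T")
  starts <- c(0, cumsum(Tvec))[seq_along(Tvec)]
  onset <- stimulus$onset
  if (is.null(onset)) {
    mid <- ceiling(length(inflow) / 2)
    b <- inflow[[mid]]
    onset <- starts[mid] + b$alpha * b$Ts  # peak q_in of the middle beat
  }
  if (onset < 0 || onset >= sum(Tvec)) stop("onset outside the run")
  ib <- findInterval(onset + 1e-12, starts)
  b <- inflow[[ib]]
  tau <- onset - starts[ib]
  if (tau > b$Ts)
    warning("mini stimulus onset falls in diastole (q_in = 0): zero-energy stimulus")
  out <- system
  out$inflow <- inflow
  if (length(out$R) == 1) out$R <- rep(out$R, length(inflow))
  win <- data.frame(t0 = onset, t1 = onset + stimulus$duration,
                    factor = 1 + stimulus$magnitude)
  out$mini <- rbind(out$mini, win)
  out
}

#' Random continuous-stimulus specification
#'
#' Per-beat multiplicative perturbations of cardiac output and peripheral
#' resistance: white noise drawn i.i.d. uniform on
#' `[-noise_halfwidth, +noise_halfwidth]` of the (possibly shifted)
#' baseline, independently for CO and R.  The analytic SD of the draws is
#' `noise_halfwidth / sqrt(3)` (2.89% of baseline at the default 5%).
#'
#' @param co_baseline baseline cardiac output (L/min).
#' @param r_baseline baseline peripheral resistance (mmHg s/mL).
#' @param noise_halfwidth half-width of the uniform noise (fraction), default 0.05.
#' @param n_beats number of cardiac cycles, default 20.
#' @param baseline_shift common fractional shift of both baselines
#'   (protocol values -0.10, 0, +0.10), default 0.
#' @param seed RNG seed.
#' @return An object of class `random_stimulus_spec`.
#' @export
random_stimulus_spec <- function(co_baseline, r_baseline,
                                 noise_halfwidth = 0.05, n_beats = 20,
                                 baseline_shift = 0, seed = 1L) {
  if (noise_halfwidth < 0) stop("noise_halfwidth must be >= 0")
  if (n_beats < 1) stop("n_beats must be >= 1")
  structure(list(co_baseline = co_baseline, r_baseline = r_baseline,
                 noise_halfwidth = noise_halfwidth, n_beats = n_beats,
                 baseline_shift = baseline_shift, seed = as.integer(seed)),
            class = "random_stimulus_spec")
}

#' Draw the per-beat (CO, R) random-stimulus sequences
#'
#' @param spec a [random_stimulus_spec()].
#' @return A data.frame with columns `beat`, `co` (L/min), `r` (mmHg s/mL);
#'   reproducible given `spec$seed`.
#' @export
make_random_stimuli <- function(spec) {
  stopifnot(inherits(spec, "random_stimulus_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  co0 <- spec$co_baseline * (1 + spec$baseline_shift)
  r0 <- spec$r_baseline * (1 + spec$baseline_shift)
  hw <- spec$noise_halfwidth
  n <- spec$n_beats
  data.frame(beat = seq_len(n),
             co = co0 * (1 + runif(n, -hw, hw)),
             r = r0 * (1 + runif(n, -hw, hw)))
}

#' Build a system whose beats follow per-beat (CO, R) sequences
#'
#' @param profile a [compliance_profile()] (or a row of
#'   [langewouters_profiles()]).
#' @param stimuli data.frame with columns `co` (L/min) and `r`, one row per
#'   beat (e.g. from [make_random_stimuli()]).
#' @param C2,L distal compliance and inertance.
#' @param T,Ts,alpha cycle timing shared by all beats.
#' @return A [windkessel_system()] with per-beat inflow and R.
#' @export
system_from_stimuli <- function(profile, stimuli, C2 = 0.1, L = 0.03,
                                T = 0.8, Ts = 0.35, alpha = 1 / 3) {
  if (is.data.frame(profile)) profile <- profile_from_row(profile[1, ])
  inflow <- lapply(stimuli$co, function(co)
    cardiac_inflow(q0_from_co(co, T, Ts, alpha), T, Ts, alpha))
  windkessel_system(profile, C2 = C2, R = stimuli$r, L = L, inflow = inflow)
}

#' PPG response metrics of a stimulus run
#'
#' The distortion is the pointwise difference between the PPG of the
#' perturbed and baseline runs (identical warm-up and beat grid).  Its
#' per-beat peak absolute value, placed at beat centers and linearly
#' interpolated, forms the response envelope; the half-width (HW) is the
#' envelope's width at 50% of its peak and the overshoot (OS) its peak
#' height.
#'
#' @param perturbed,baseline `wk4_sim` results on the same grid.
#' @param transfer a [pv_spec()] used to translate pressure to PPG when the
#'   runs were simulated without one.
#' @return A list of class `response_metrics`: `distortion`
#'   ([signal_trace()]), `envelope` (data.frame `t`, `peak`), `HW` (s,
#'   `NA` if the peak is zero), `OS`, `peak_response`.
#' @export
response_metrics <- function(perturbed, baseline, transfer = NULL) {
  stopifnot(inherits(perturbed, "wk4_sim"), inherits(baseline, "wk4_sim"))
  if (perturbed$dt != baseline$dt ||
      length(perturbed$p_p$values) != length(baseline$p_p$values) ||
      !identical(perturbed$beat_starts, baseline$beat_starts))
    stop("perturbed and baseline runs are not on the same grid")
  get_ppg <- function(sim) {
    if (!is.null(sim$ppg)) sim$ppg$values
    else if (!is.null(transfer)) pv_transfer(sim$p_p$values, transfer)
    else stop("no ppg in the runs and no transfer given")
  }
  d <- get_ppg(perturbed) - get_ppg(baseline)
  dt <- perturbed$dt
  bs <- perturbed$beat_starts
  ends <- c(bs[-1] - 1L, length(d))
  peak <- vapply(seq_along(bs), function(i) max(abs(d[bs[i]:ends[i]])),
                 numeric(1))
  tc <- (bs + ends) / 2 * dt
  env <- data.frame(t = tc, peak = peak)
  os <- max(peak)
  hw <- envelope_halfwidth(tc, peak)
  structure(list(distortion = signal_trace(d, dt, "a.u."), envelope = env,
                 HW = hw, OS = os, peak_response = os),
            class = "response_metrics")
}

# width of the linearly interpolated envelope at 50% of its peak
envelope_halfwidth <- function(t, peak) {
  if (max(peak) <= 0) return(NA_real_)
  half <- max(peak) / 2
  ip <- which.max(peak)
  cross <- function(i, j) {
    # linear interpolation of the crossing time between samples i and j
    t[i] + (half - peak[i]) * (t[j] - t[i]) / (peak[j] - peak[i])
  }
  # left crossing: last upward crossing before the peak
  tl <- t[1]
  for (i in seq_len(max(ip - 1, 0))) {
    if (peak[i] < half && peak[i + 1] >= half) tl <- cross(i, i + 1)
  }
  # right crossing: first downward crossing after the peak
  tr <- t[length(t)]
  for (i in seq(ip, length(peak) - 1)) {
    if (peak[i] >= half && peak[i + 1] < half) {
      tr <- cross(i, i + 1)
      break
    }
  }
  tr - tl
}

#' Simulate the hemodynamic sweep protocol
#'
#' Cartesian product of compliance profiles, peripheral resistances
#' (protocol default 0.7 to 1.3 in steps of 0.2 mmHg s/mL) and cardiac
#' outputs (4.25, 5.1, 5.95 L/min).  Each combination is simulated to
#' periodic steady state; rows whose systolic pressure leaves the
#' 80--220 mmHg band are flagged `discarded` (and their stimulus metrics
#' are still reported).  When `stimulus` is given, a perturbed run is
#' simulated on the same grid and half-width/overshoot of the PPG response
#' are added.  Individual simulation failures are recorded per row, not
#' fatal.
#'
#' @param profiles data.frame as from [langewouters_profiles()].
#' @param R_values,CO_values factor levels of the sweep.
#' @param C2,L,T,Ts,alpha shared system parameters.
#' @param n_beats beats per run (default 20).
#' @param stimulus optional [pulse_stimulus()].
#' @param stimuli_fun optional function(profile_row, R, CO) returning a
#'   per-beat data.frame(co, r) of continuous stimuli (overrides the
#'   constant baseline); used by the random-stimulation protocol.
#' @param transfer the pressure-volume transfer used for PPG.  The default
#'   is a fixed, generalized mid-range transfer so response amplitudes are
#'   comparable across compliance profiles (a per-profile personalized
#'   transfer would confound the overshoot comparison with the site gain).
#' @return data.frame with one row per grid point: profile parameters, R,
#'   CO, SBP, DBP, MAP, mean C1, `HW_s`, `OS_au` (when a stimulus was
#'   given), `discarded` and `error` columns.
#' @export
sweep_grid <- function(profiles = langewouters_profiles(),
                       R_values = c(0.7, 0.9, 1.1, 1.3),
                       CO_values = c(4.25, 5.1, 5.95),
                       C2 = 0.1, L = 0.03, T = 0.8, Ts = 0.35,
                       alpha = 1 / 3, n_beats = 20, stimulus = NULL,
                       stimuli_fun = NULL,
                       transfer = pv_spec(Am_v = 5, P0_v = 25, P1_v = 30)) {
  if (nrow(profiles) == 0 || !length(R_values) || !length(CO_values))
    stop("empty sweep factors")
  grid <- expand.grid(profile_id = profiles$profile_id, R = R_values,
                      CO = CO_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    prow <- profiles[profiles$profile_id == grid$profile_id[g], ]
    R <- grid$R[g]
    CO <- grid$CO[g]
    row <- data.frame(profile_id = prow$profile_id, Am = prow$Am,
                      P0 = prow$P0, P1 = prow$P1, l = prow$l, R = R,
                      CO = CO, C2 = C2, L = L, SBP = NA_real_,
                      DBP = NA_real_, MAP = NA_real_, C1_mean = NA_real_,
                      HW_s = NA_real_, OS_au = NA_real_,
                      acf_hw_s = NA_real_,
                      discarded = NA, error = NA_character_)
    res <- tryCatch({
      profile <- profile_from_row(prow)
      if (is.null(stimuli_fun)) {
        inflow <- cardiac_inflow(q0_from_co(CO, T, Ts, alpha), T, Ts, alpha)
        sys <- windkessel_system(profile, C2 = C2, R = R, L = L,
                                 inflow = inflow)
        sys <- list(sys = sys, n_beats = n_beats)
      } else {
        st <- stimuli_fun(prow, R, CO)
        sys <- list(sys = system_from_stimuli(profile, st, C2 = C2, L = L,
                                              T = T, Ts = Ts, alpha = alpha),
                    n_beats = NULL)
      }
      base <- simulate_wk4(sys$sys, n_beats = sys$n_beats,
                           transfer = transfer)
      row$SBP <- median(base$sbp)
      row$DBP <- median(base$dbp)
      row$MAP <- mean(base$p_p$values)
      row$C1_mean <- mean(base$c1_t$values)
      row$acf_hw_s <- tryCatch({
        ar <- signal_acf(base$ppg$values, max_lag = round(5 / base$dt))
        acf_halfwidth(ar, base$dt)
      }, error = function(e) NA_real_)
      row$discarded <- any(base$sbp > 220 | base$sbp < 80)
      if (!is.null(stimulus)) {
        pert_sys <- if (stimulus$kind == "sv")
          make_sv_pulse(sys$sys, stimulus, n_beats = sys$n_beats)
        else make_mini_pulse(sys$sys, stimulus, n_beats = sys$n_beats)
        pert <- simulate_wk4(pert_sys, transfer = transfer)
        m <- response_metrics(pert, base)
        row$HW_s <- m$HW
        row$OS_au <- m$OS
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[g]] <- res
  }
  do.call(rbind, rows)
}
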