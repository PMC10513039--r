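#' Pressure-dependent central compliance
#'
#' Evaluates the Langewouters volume compliance
#' \eqn{C_1(p) = A_m l / (\pi P_1 (1 + ((p - P_0)/P_1)^2))} (mL/mmHg).
#' Strictly positive, symmetric about and maximal at \eqn{p = P_0}.
#'
#' @param profile a [compliance_profile()].
#' @param p_c central pressure (mmHg), scalar or vector; must be finite.
#' @return Compliance value(s) in mL/mmHg.
#' @export
compliance_c1 <- function(profile, p_c) {
  stopifnot(inherits(profile, "compliance_profile"))
  if (!is.numeric(p_c) || !all(is.finite(p_c)))
    stop("p_c must be finite numeric")
  z <- (p_c - profile$P0) / profile$P1
  profile$Am * profile$l / (pi * profile$P1 * (1 + z^2))
}

#' Ejection flow at a time within the cycle
#'
#' @param inflow a [cardiac_inflow()].
#' @param t time since beat onset (s), scalar or vector, within `[0, T]`.
#' @return Flow (mL/s).
#' @export
inflow_value <- function(inflow, t) {
  stopifnot(inherits(inflow, "cardiac_inflow"))
  if (!is.numeric(t) || !all(is.finite(t))) stop("t must be finite numeric")
  if (any(t < 0 | t > inflow$T)) stop("t outside [0, T]")
  aTs <- inflow$alpha * inflow$Ts
  q <- numeric(length(t))
  up <- t <= aTs
  ej <- !up & t <= inflow$Ts
  q[up] <- inflow$q0 * sin(pi * t[up] / (2 * aTs))
  q[ej] <- inflow$q0 * cos(pi * (t[ej] - aTs) / (4 * aTs))
  q
}

# closed-form integral of the unit-q0 ejection waveform over one cycle
unit_stroke_volume <- function(T, Ts, alpha = 1 / 3) {
  aTs <- alpha * Ts
  # sin branch: 2*aTs/pi; cos branch: (4*aTs/pi) * sin(pi*(Ts - aTs)/(4*aTs))
  2 * aTs / pi + (4 * aTs / pi) * sin(pi * (Ts - aTs) / (4 * aTs))
}

#' Stroke volume of an inflow specification
#'
#' Closed-form integral of the ejection waveform over one cardiac cycle
#' (mL).  For \eqn{\alpha = 1/3} this reduces to \eqn{2 q_0 T_s / \pi}.
#'
#' @param inflow a [cardiac_inflow()].
#' @return Stroke volume (mL).
#' @export
stroke_volume <- function(inflow) {
  stopifnot(inherits(inflow, "cardiac_inflow"))
  inflow$q0 * unit_stroke_volume(inflow$T, inflow$Ts, inflow$alpha)
}

#' Peak flow needed to achieve a target cardiac output
#'
#' Inverts the stroke-volume integral: returns the `q0` for which
#' SV x HR equals the requested cardiac output.
#'
#' @param CO cardiac output (L/min); >= 0.
#' @param T cardiac period (s).
#' @param Ts ejection duration (s).
#' @param alpha peak-time fraction, default 1/3.
#' @return Peak flow q0 (mL/s).
#' @examples
#' q0_from_co(5.95, T = 0.8, Ts = 0.35)  # ~ 356.1 mL/s
#' @export
q0_from_co <- function(CO, T = 0.8, Ts = 0.35, alpha = 1 / 3) {
  if (!is.finite(CO) || CO < 0) stop("CO must be >= 0")
  if (!(Ts > 0 && Ts < T)) stop("need 0 < Ts < T")
  sv <- CO * 1000 / 60 * T  # mL per beat
  sv / unit_stroke_volume(T, Ts, alpha)
}

# expand the inflow list of a system to n_beats (recycling a single beat)
expand_inflow <- function(system, n_beats) {
  inflow <- system$inflow
  if (is.null(n_beats)) return(inflow)
  if (length(inflow) == 1 && n_beats > 1)
    inflow <- rep(inflow, n_beats)
  if (length(inflow) != n_beats)
    stop("n_beats does not match the length of the inflow sequence")
  inflow
}

beat_R <- function(system, i, n_beats) {
  if (length(system$R) == 1) system$R else system$R[[i]]
}

#' Simulate the modified Windkessel system
#'
#' Integrates the coupled system (central flow q, central pressure p_c,
#' peripheral pressure p_p) beat by beat with an adaptive Dormand-Prince
#' RK45 scheme, sampling on a fixed `dt` grid.  Initial conditions are
#' p_p = p_c = 80 mmHg, q = 0; warm-up beats (copies of the first beat) are
#' integrated first and discarded, stopping early once the cycle-to-cycle
#' max |change in p_p| falls below 0.1 mmHg.
#'
#' Two formulations are available and must agree (cross-check contract):
#' `"first_order"` integrates the three-state system in compiled code;
#' `"third_order"` integrates the equivalent scalar third-order ODE in p_p
#' (compliance evaluated at the reconstructed central pressure) in plain R
#' and serves as the independent oracle.
#'
#' @param system a [windkessel_system()].
#' @param n_beats number of beats to simulate (default: length of the
#'   inflow sequence; a single inflow beat is recycled).
#' @param dt output sample interval (s), default 0.01.
#' @param warmup_beats maximum warm-up beats, default 10.
#' @param rtol relative tolerance of the integrator, default 1e-6.
#' @param formulation `"first_order"` (compiled, default) or
#'   `"third_order"` (plain-R oracle).
#' @param transfer optional [pv_spec()]; when given, a `ppg` trace is added.
#' @return A list of class `wk4_sim` with `signal_trace` elements `p_p`,
#'   `p_c`, `q`, `c1_t` (and `ppg` when `transfer` is given), integer
#'   `beat_starts` (1-based sample indices of beat onsets), per-beat `sbp`,
#'   `dbp`, `map`, and `sbp_ok` (FALSE when any beat's systolic pressure
#'   leaves the physiological 80--220 mmHg acceptance band).
#' @examples
#' sys <- windkessel_system(compliance_profile(3.5, 50.4, 42.3),
#'                          C2 = 0.1, R = 1.4, L = 0.03,
#'                          inflow = cardiac_inflow(q0_from_co(5.95)))
#' sim <- simulate_wk4(sys, n_beats = 5)
#' mean(sim$p_p$values)  # ~ R * CO = 138.8 mmHg
#' @export
simulate_wk4 <- function(system, n_beats = NULL, dt = 0.01,
                         warmup_beats = 10, rtol = 1e-6,
                         formulation = c("first_order", "third_order"),
                         transfer = NULL) {
  stopifnot(inherits(system, "windkessel_system"))
  formulation <- match.arg(formulation)
  inflow <- expand_inflow(system, n_beats)
  n_beats <- length(inflow)
  if (n_beats < 1) stop("n_beats must be >= 1")
  atol <- 1e-8

  mini <- system$mini
  if (is.null(mini))
    mini <- data.frame(t0 = numeric(0), t1 = numeric(0), factor = numeric(0))

  step_beat <- function(state, pars, t0, beat_index) {
    if (formulation == "first_order") {
      wk4_integrate_beat(state, pars, t0, dt, rtol, atol, beat_index)
    } else {
      wk4_integrate_beat_p3(state, pars, t0, dt, rtol, atol, beat_index)
    }
  }

  make_pars <- function(beat, R, shift = 0) {
    list(Am = system$c1_profile$Am, P0 = system$c1_profile$P0,
         P1 = system$c1_profile$P1, l = system$c1_profile$l,
         C2 = system$C2, R = R, L = system$L,
         q0 = beat$q0, T = beat$T, Ts = beat$Ts, alpha = beat$alpha,
         mini_t0 = mini$t0 + shift, mini_t1 = mini$t1 + shift,
         mini_factor = mini$factor)
  }

  state <- init_state(system, formulation)

  # ---- warm-up: copies of beat 1, early stop on cycle convergence --------
  wb <- inflow[[1]]
  wpars <- make_pars(wb, beat_R(system, 1, n_beats), shift = Inf)
  t <- 0
  prev_pp <- NULL
  for (w in seq_len(warmup_beats)) {
    res <- step_beat(state, wpars, t, beat_index = -w)
    state <- res$state
    t <- t + wb$T
    if (!is.null(prev_pp) && length(prev_pp) == length(res$p_p) &&
        max(abs(res$p_p - prev_pp)) < 0.1) {
      prev_pp <- res$p_p
      break
    }
    prev_pp <- res$p_p
  }

  # ---- scheduled beats, timeline restarted at 0 --------------------------
  t <- 0
  beat_starts <- integer(n_beats)
  acc <- vector("list", n_beats)
  n_total <- 0L
  for (i in seq_len(n_beats)) {
    beat <- inflow[[i]]
    pars <- make_pars(beat, beat_R(system, i, n_beats))
    res <- step_beat(state, pars, t, beat_index = i)
    state <- res$state
    beat_starts[i] <- n_total + 1L
    n_total <- n_total + length(res$p_p)
    acc[[i]] <- res
    t <- t + beat$T
  }

  p_p <- unlist(lapply(acc, `[[`, "p_p"), use.names = FALSE)
  p_c <- unlist(lapply(acc, `[[`, "p_c"), use.names = FALSE)
  q <- unlist(lapply(acc, `[[`, "q"), use.names = FALSE)
  c1 <- unlist(lapply(acc, `[[`, "c1"), use.names = FALSE)
  q_in <- unlist(lapply(acc, `[[`, "q_in"), use.names = FALSE)

  sbp <- vapply(acc, function(r) max(r$p_p), numeric(1))
  dbp <- vapply(acc, function(r) min(r$p_p), numeric(1))
  map <- vapply(acc, function(r) mean(r$p_p), numeric(1))

  out <- structure(list(
    p_p = signal_trace(p_p, dt, "mmHg"),
    p_c = signal_trace(p_c, dt, "mmHg"),
    q = signal_trace(q, dt, "mL/s"),
    c1_t = signal_trace(c1, dt, "mL/mmHg"),
    q_in = signal_trace(q_in, dt, "mL/s"),
    beat_starts = beat_starts,
    sbp = sbp, dbp = dbp, map = map,
    sbp_ok = all(sbp >= 80 & sbp <= 220),
    dt = dt), class = "wk4_sim")
  if (!is.null(transfer)) out$ppg <- pv_transfer(out$p_p, transfer)
  out
}

# both formulations carry the physical state (q, p_c, p_p)
init_state <- function(system, formulation) c(0, 80, 80)

#' @export
print.wk4_sim <- function(x, ...) {
  cat(sprintf(
    "<wk4_sim> %d beats, %d samples @ %g s; MAP %.1f mmHg; SBP ok: %s\n",
    length(x$beat_starts), length(x$p_p$values), x$dt,
    mean(x$p_p$values), x$sbp_ok))
  invisible(x)
}

#' Translate peripheral pressure into a PPG signal
#'
#' Applies the arctangent pressure-volume relationship of a [pv_spec()]:
#' monotonically increasing in pressure, scaled by the sensor gain.
#'
#' @param p_p peripheral pressure, a [signal_trace()] or numeric vector.
#' @param transfer a [pv_spec()].
#' @return A `signal_trace` (unit "a.u.") if `p_p` is a trace, else numeric.
#' @export
pv_transfer <- function(p_p, transfer) {
  stopifnot(inherits(transfer, "pv_spec"))
  v <- trace_values(p_p)
  ppg <- transfer$gain * transfer$Am_v *
    (0.5 + atan((v - transfer$P0_v) / transfer$P1_v) / pi) + transfer$offset
  if (inherits(p_p, "signal_trace")) signal_trace(ppg, p_p$dt, "a.u.")
  else ppg
}
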