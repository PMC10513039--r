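#' Langewouters compliance profile
#'
#' Parameters of the arctangent pressure--area law of a central (aortic)
#' segment.  The volume compliance of a unit-length segment is its pressure
#' derivative, \deqn{C_1(p) = \frac{A_m l}{\pi P_1 (1 + ((p - P_0)/P_1)^2)},}
#' maximal at \eqn{p = P_0}.
#'
#' @param Am maximal cross-sectional area (cm^2); must be > 0.
#' @param P0 transmural pressure of maximal compliance (mmHg).
#' @param P1 compliance-steepness pressure (mmHg); must be > 0.
#' @param l unit vessel length (cm); must be > 0.
#' @return An object of class `compliance_profile`.
#' @examples
#' aorta1 <- compliance_profile(Am = 3.5, P0 = 50.4, P1 = 42.3)
#' compliance_c1(aorta1, 50.4)  # maximum: Am / (pi * P1)
#' @export
compliance_profile <- function(Am, P0, P1, l = 1) {
  stopifnot(is.numeric(Am), is.numeric(P0), is.numeric(P1), is.numeric(l))
  if (!is.finite(Am) || Am <= 0) stop("Am must be a positive finite number")
  if (!is.finite(P1) || P1 <= 0) stop("P1 must be a positive finite number")
  if (!is.finite(l) || l <= 0) stop("l must be a positive finite number")
  if (!is.finite(P0)) stop("P0 must be finite")
  structure(list(Am = Am, P0 = P0, P1 = P1, l = l),
            class = "compliance_profile")
}

#' @export
print.compliance_profile <- function(x, ...) {
  cat(sprintf(
    "<compliance_profile> Am = %.3g cm^2, P0 = %.3g mmHg, P1 = %.3g mmHg, l = %.3g cm\n",
    x$Am, x$P0, x$P1, x$l))
  invisible(x)
}

#' Analytic cardiac ejection waveform for one beat
#'
#' Half-sine upstroke followed by a quarter-cosine decay:
#' \eqn{q_{in}(t) = q_0 \sin(\pi t / (2\alpha T_s))} on \eqn{[0, \alpha T_s]},
#' \eqn{q_0 \cos(\pi (t-\alpha T_s)/(4 \alpha T_s))} on
#' \eqn{(\alpha T_s, T_s]}, and 0 during diastole.  With the default
#' \eqn{\alpha = 1/3} the pulse is continuous and reaches zero exactly at
#' \eqn{T_s}; its integral over the cycle is the stroke volume.
#'
#' @param q0 peak ejection flow (mL/s); >= 0.
#' @param T cardiac period (s).
#' @param Ts ejection duration (s); 0 < Ts < T.
#' @param alpha peak-time fraction in (0, 1); default 1/3.
#' @return An object of class `cardiac_inflow`.
#' @export
cardiac_inflow <- function(q0, T = 0.8, Ts = 0.35, alpha = 1 / 3) {
  stopifnot(is.numeric(q0), is.numeric(T), is.numeric(Ts), is.numeric(alpha))
  if (!is.finite(q0) || q0 < 0) stop("q0 must be >= 0")
  if (!(Ts > 0 && Ts < T)) stop("need 0 < Ts < T")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(q0 = q0, T = T, Ts = Ts, alpha = alpha),
            class = "cardiac_inflow")
}

#' Four-element Windkessel system
#'
#' Bundles the pressure-dependent central compliance profile, the constant
#' distal elements (C2, R, L) and a per-beat inflow sequence.  `R` may be a
#' scalar or one value per beat (slowly varying peripheral resistance).
#'
#' @param c1_profile a [compliance_profile()].
#' @param C2 distal compliance (mL/mmHg).
#' @param R peripheral resistance (mmHg s/mL), scalar or per beat.
#' @param L inertance (mmHg s^2/mL).
#' @param inflow a [cardiac_inflow()] or a list of them (one per beat).
#' @return An object of class `windkessel_system`.
#' @examples
#' sys <- windkessel_system(
#'   compliance_profile(3.5, 50.4, 42.3),
#'   C2 = 0.1, R = 1.4, L = 0.03,
#'   inflow = cardiac_inflow(q0_from_co(5.95, 0.8, 0.35))
#' )
#' @export
windkessel_system <- function(c1_profile, C2, R, L, inflow) {
  stopifnot(inherits(c1_profile, "compliance_profile"))
  if (!all(is.finite(C2)) || C2 <= 0) stop("C2 must be > 0")
  if (!all(is.finite(R)) || any(R <= 0)) stop("R must be > 0")
  if (!all(is.finite(L)) || L <= 0) stop("L must be > 0")
  if (inherits(inflow, "cardiac_inflow")) inflow <- list(inflow)
  if (length(inflow) == 0) stop("inflow must be non-empty")
  if (!all(vapply(inflow, inherits, logical(1), "cardiac_inflow")))
    stop("inflow must be cardiac_inflow objects")
  if (length(R) > 1 && length(R) != length(inflow))
    stop("per-beat R must match the number of inflow beats")
  structure(list(c1_profile = c1_profile, C2 = C2, R = R, L = L,
                 inflow = inflow, mini = NULL),
            class = "windkessel_system")
}

#' @export
print.windkessel_system <- function(x, ...) {
  cat(sprintf(
    "<windkessel_system> %d beat(s); C2 = %.3g, R = %.3g%s, L = %.3g\n",
    length(x$inflow), x$C2, x$R[1],
    if (length(x$R) > 1) " (per beat)" else "", x$L))
  print(x$c1_profile)
  invisible(x)
}

#' Uniformly sampled signal trace
#'
#' @param values numeric vector of samples (finite).
#' @param dt sample interval (s), default 0.01.
#' @param unit unit label, e.g. "mmHg", "mL/s", "a.u.".
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, dt = 0.01, unit = "a.u.") {
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("values must be finite numeric")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive number")
  structure(list(values = as.numeric(values), dt = dt, unit = unit),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ dt = %g s [%s]\n",
              length(x$values), x$dt, x$unit))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

# coerce numeric-or-trace to numeric values
trace_values <- function(x) {
  if (inherits(x, "signal_trace")) x$values else as.numeric(x)
}

#' Pressure-volume transfer specification
#'
#' Site-level arctangent pressure--volume relationship used to translate
#' peripheral pressure into a PPG signal (arbitrary units):
#' \deqn{PPG = gain \cdot A_{m,v} (1/2 + \arctan((p - P_{0,v})/P_{1,v})/\pi)
#' + offset.}  Gain and offset model the sensor-skin optical coupling.
#'
#' @param Am_v site maximal area (cm^2).
#' @param P0_v site pressure of maximal compliance (mmHg).
#' @param P1_v site steepness pressure (mmHg).
#' @param gain coupling scale (> 0), default 1.
#' @param offset baseline shift (a.u.), default 0.
#' @return An object of class `pv_spec`.
#' @export
pv_spec <- function(Am_v, P0_v, P1_v, gain = 1, offset = 0) {
  if (!is.finite(Am_v) || Am_v <= 0) stop("Am_v must be > 0")
  if (!is.finite(P1_v) || P1_v <= 0) stop("P1_v must be > 0")
  if (!is.finite(gain) || gain <= 0) stop("gain must be > 0")
  structure(list(Am_v = Am_v, P0_v = P0_v, P1_v = P1_v,
                 gain = gain, offset = offset),
            class = "pv_spec")
}

#' Derive a site transfer from a compliance profile
#'
#' Convenience constructor: uses the same arctangent parameters as the
#' central compliance profile (the area function whose derivative is the
#' compliance), a personalized reading of the pressure-volume translation.
#'
#' @param profile a [compliance_profile()].
#' @param gain,offset sensor coupling parameters.
#' @return A [pv_spec()].
#' @export
pv_spec_from_profile <- function(profile, gain = 1, offset = 0) {
  pv_spec(profile$Am, profile$P0, profile$P1, gain = gain, offset = offset)
}
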