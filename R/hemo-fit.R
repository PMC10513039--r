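# Per-subject hemodynamic estimation from measured BP and stroke volume:
# grid-of-profiles Windkessel fitting (lowest-RMSE profile wins), quick
# model-free estimators, and the cross-model consistency discard.

# build the per-beat inflow sequence from detected feet and measured SV
inflow_from_beats <- function(intervals, sv_per_beat, Ts = 0.35,
                              alpha = 1 / 3) {
  lapply(seq_along(intervals), function(i) {
    T <- intervals[i]
    Tse <- min(Ts, 0.5 * T)
    q0 <- sv_per_beat[i] / unit_stroke_volume(T, Tse, alpha)
    cardiac_inflow(q0, T, Tse, alpha)
  })
}

# RMSE between a simulated pressure run and the measured segment.  The
# measured segment starts at a detected foot, which lags the true inflow
# onset by a few samples, and each detected foot is quantized to the
# sample grid; the comparison therefore finds a global alignment lag and
# then lets every beat take a small fractional lag of its own (the
# quantization jitter would otherwise put a ~1 mmHg floor under the RMSE
# that masks genuine profile differences).
wk4_rmse <- function(profile, R, L, C2, inflow, bp_seg, dt, max_lag = 15) {
  sys <- windkessel_system(profile, C2 = C2, R = R, L = L, inflow = inflow)
  sim <- tryCatch(simulate_wk4(sys, dt = dt), error = function(e) NULL)
  if (is.null(sim)) return(Inf)
  s <- sim$p_p$values
  m <- min(length(s), length(bp_seg))
  pad <- max_lag + 4
  i <- pad:(m - pad)
  if (length(i) < 10) return(Inf)
  shift_s <- function(idx, lag) {
    fl <- floor(lag)
    fr <- lag - fl
    s[idx + fl] * (1 - fr) + s[idx + fl + 1] * fr
  }
  rmse_at <- function(lag) sqrt(mean((shift_s(i, lag) - bp_seg[i])^2))
  lags <- seq(-max_lag, max_lag, by = 2)
  coarse <- vapply(lags, rmse_at, numeric(1))
  l0 <- lags[which.min(coarse)]
  fine_lags <- l0 + seq(-1.75, 1.75, by = 0.25)
  fine <- vapply(fine_lags, rmse_at, numeric(1))
  g <- fine_lags[which.min(fine)]
  # per-beat refinement around the global lag
  bs <- sim$beat_starts
  ends <- c(bs[-1] - 1L, length(s))
  sse <- 0
  n_tot <- 0
  for (b in seq_along(bs)) {
    idx <- max(bs[b], pad):min(ends[b], m - pad)
    if (length(idx) < 5) next
    errs <- vapply(g + seq(-1.25, 1.25, by = 0.25), function(lag)
      sum((shift_s(idx, lag) - bp_seg[idx])^2), numeric(1))
    sse <- sse + min(errs)
    n_tot <- n_tot + length(idx)
  }
  if (n_tot < 10) return(min(fine))
  sqrt(sse / n_tot)
}

#' Fit the Windkessel model to a measured BP record
#'
#' For each candidate compliance profile, (R, L, C2) are optimized
#' (Nelder-Mead on log parameters, seeded at R = MAP/CO, C2 = 0.1,
#' L = 0.03) to minimize the RMSE between the simulated and measured
#' peripheral pressure waveform, with the per-beat inflow set from the
#' measured stroke volumes.  The profile with the lowest RMSE wins; ties
#' break to the lowest profile index.
#'
#' @param bp measured blood pressure, a [signal_trace()] or numeric vector
#'   at 100 Hz; at least 10 beats.
#' @param sv_per_beat measured stroke volume per beat (mL), aligned to the
#'   beats detected in `bp`; a scalar is recycled.
#' @param profiles candidate profiles (data.frame as from
#'   [langewouters_profiles()]).
#' @param n_fit_beats number of beats fitted (default 8; the record may be
#'   longer).
#' @param maxit Nelder-Mead iterations per profile, default 60.
#' @param Ts,alpha assumed ejection timing.
#' @return A list of class `hemo_estimate`: `profile_id`, `R_fit`, `L_fit`,
#'   `C2_fit`, `rmse` (mmHg), `per_profile` (RMSE per candidate).
#' @export
fit_windkessel <- function(bp, sv_per_beat,
                           profiles = langewouters_profiles(),
                           n_fit_beats = 8, maxit = 60, Ts = 0.35,
                           alpha = 1 / 3) {
  x <- trace_values(bp)
  dt <- if (inherits(bp, "signal_trace")) bp$dt else 0.01
  beats <- detect_beats(x, fs = 1 / dt)
  if (length(beats$intervals) < 10) stop("need at least 10 beats")
  nb <- min(n_fit_beats, length(beats$intervals))
  i0 <- beats$onsets[1]
  i1 <- beats$onsets[nb + 1] - 1L
  bp_seg <- x[i0:i1]
  intervals <- round(beats$intervals[seq_len(nb)] / dt) * dt
  sv <- rep_len(sv_per_beat, nb)
  inflow <- inflow_from_beats(intervals, sv, Ts, alpha)
  map <- mean(bp_seg)
  co_mls <- sum(sv) / sum(intervals)
  r_init <- map / co_mls

  th0 <- log(c(r_init, 0.03, 0.1))
  fit_one <- function(pi, th_start, iters) {
    profile <- profile_from_row(profiles[pi, ])
    obj <- function(th) {
      wk4_rmse(profile, exp(th[1]), exp(th[2]), exp(th[3]), inflow,
               bp_seg, dt)
    }
    optim(th_start, obj, method = "Nelder-Mead",
          control = list(maxit = iters, reltol = 1e-6))
  }
  # two-stage search: a cheap screen ranks all profiles, then the leading
  # candidates are refined (the objective is unimodal per profile; the
  # screen only needs the ranking roughly right)
  screen <- lapply(seq_len(nrow(profiles)), fit_one, th_start = th0,
                   iters = max(10, maxit %/% 4))
  per_profile <- vapply(screen, `[[`, numeric(1), "value")
  top <- order(per_profile)[seq_len(min(6, nrow(profiles)))]
  best <- NULL
  for (pi in top) {
    opt <- fit_one(pi, screen[[pi]]$par, maxit)
    per_profile[pi] <- opt$value
    if (is.null(best) || opt$value < best$rmse - 1e-12) {
      best <- list(profile_id = profiles$profile_id[pi],
                   R_fit = exp(opt$par[1]), L_fit = exp(opt$par[2]),
                   C2_fit = exp(opt$par[3]), rmse = opt$value)
    }
  }
  if (!is.finite(best$rmse))
    stop("optimizer failed to converge on every candidate profile")
  structure(c(best, list(per_profile = per_profile, R_init = r_init)),
            class = "hemo_estimate")
}

#' @export
print.hemo_estimate <- function(x, ...) {
  cat(sprintf(
    "<hemo_estimate> profile %d: R = %.3f, L = %.4f, C2 = %.4f (RMSE %.3f mmHg)\n",
    x$profile_id, x$R_fit, x$L_fit, x$C2_fit, x$rmse))
  invisible(x)
}

#' Model-free quick estimates of R and relative C1
#'
#' `R_alt = MAP / CO` (mmHg s/mL, CO in mL/s) and
#' `C1_alt = median(AC_ppg) / median(PP_bp)` (a.u./mmHg, a *relative*
#' compliance measure: it scales with the PPG gain).
#'
#' @param bp,ppg aligned [signal_trace()]s (or numeric at 100 Hz).
#' @param sv_per_beat stroke volume per beat (mL), recycled as needed.
#' @return list(`R_alt`, `C1_alt`, `MAP`, `CO_mls`).
#' @export
quick_estimates <- function(bp, ppg, sv_per_beat) {
  xb <- trace_values(bp)
  xp <- trace_values(ppg)
  dt <- if (inherits(bp, "signal_trace")) bp$dt else 0.01
  beats <- detect_beats(xb, fs = 1 / dt)
  nb <- length(beats$intervals)
  sv <- rep_len(sv_per_beat, nb)
  co_mls <- sum(sv) / sum(beats$intervals)
  if (co_mls <= 0) stop("CO must be positive")
  map <- mean(xb)
  pp <- vapply(seq_len(nb), function(i) {
    s <- beats$onsets[i]:(beats$onsets[i + 1] - 1L)
    max(xb[s]) - min(xb[s])
  }, numeric(1))
  acp <- vapply(seq_len(nb), function(i) {
    s <- beats$onsets[i]:(beats$onsets[i + 1] - 1L)
    max(xp[s]) - min(xp[s])
  }, numeric(1))
  list(R_alt = map / co_mls, C1_alt = median(acp) / median(pp),
       MAP = map, CO_mls = co_mls)
}

#' Cross-model consistency filter
#'
#' A sample is kept iff the Windkessel-fitted R and the MAP/CO estimate
#' agree within `threshold` (relative, default 30%), and — when per-window
#' compliance columns `C1_fit`/`C1_alt` are present with enough rows — the
#' Spearman correlation between them is positive.
#'
#' @param estimates data.frame with columns `R_fit` and `R_alt` (optionally
#'   `C1_fit`, `C1_alt`).
#' @param threshold relative R disagreement tolerance, default 0.30.
#' @return The data.frame with a logical `consistent` column added.
#' @export
consistency_filter <- function(estimates, threshold = 0.30) {
  stopifnot(all(c("R_fit", "R_alt") %in% names(estimates)))
  keep <- abs(estimates$R_fit - estimates$R_alt) / estimates$R_alt <= threshold
  if (all(c("C1_fit", "C1_alt") %in% names(estimates)) &&
      nrow(estimates) >= 3 &&
      sd(estimates$C1_fit) > 0 && sd(estimates$C1_alt) > 0) {
    rho <- cor(estimates$C1_fit, estimates$C1_alt, method = "spearman")
    keep <- keep & (rho > 0)
  }
  estimates$consistent <- keep
  estimates
}
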