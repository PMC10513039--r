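# Beat segmentation and per-beat morphology of PPG-like pulsatile signals.
# The detector is prominence-based (parameter-light and scale-invariant):
# systolic peaks are local maxima with prominence >= 0.3x the window
# peak-to-peak range and minimum separation 0.4x the median peak interval;
# beat feet are the minima between consecutive peaks.

# prominence of each local maximum (classic definition: height above the
# highest of the two minima separating it from the nearest higher point)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p)]
    hi <- which(left > h)
    lmin <- min(left[seq(if (length(hi)) max(hi) else 1, p)])
    right <- x[p:length(x)]
    hi <- which(right > h)
    rmin <- min(right[seq(1, if (length(hi)) min(hi) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect beats in a pulsatile trace
#'
#' @param trace a [signal_trace()] (or numeric at 100 Hz) of at least 3 s.
#' @param fs sampling rate (Hz); taken from the trace when available.
#' @return A list of class `beat_series`: `onsets` and `peaks` (1-based
#'   sample indices; onsets are the beat feet), `intervals` (foot-to-foot,
#'   s), `AC` (per-beat peak-to-peak amplitude), `DC` (per-beat mean).
#'   Beats are the spans between consecutive feet.
#' @export
detect_beats <- function(trace, fs = NULL) {
  x <- trace_values(trace)
  if (is.null(fs)) fs <- if (inherits(trace, "signal_trace")) 1 / trace$dt else 100
  if (length(x) < 3 * fs) stop("trace shorter than 3 s")
  cand <- local_maxima(x)
  if (length(cand) < 2) stop("fewer than 2 detectable beats")
  prom <- peak_prominence(x, cand)
  # prominence threshold is local (10-s blocks) so that slow baseline or
  # gain drift does not inflate the reference peak-to-peak range
  block <- pmin(((cand - 1) %/% round(10 * fs)) + 1,
                max(1, ceiling(length(x) / round(10 * fs))))
  p2p_of <- vapply(seq_len(max(block)), function(b) {
    i0 <- (b - 1) * round(10 * fs) + 1
    i1 <- min(length(x), b * round(10 * fs))
    max(x[i0:i1]) - min(x[i0:i1])
  }, numeric(1))
  keep <- cand[prom >= 0.3 * p2p_of[block]]
  if (length(keep) < 2) stop("fewer than 2 detectable beats")
  # enforce minimum separation 0.4x the median interval, keeping the taller
  min_sep <- 0.4 * median(diff(keep))
  ord <- order(x[keep], decreasing = TRUE)
  sel <- logical(length(keep))
  for (i in ord) {
    if (!any(sel & abs(keep - keep[i]) < min_sep)) sel[i] <- TRUE
  }
  peaks <- sort(keep[sel])
  if (length(peaks) < 2) stop("fewer than 2 detectable beats")
  # feet: minima between consecutive peaks
  feet <- vapply(seq_len(length(peaks) - 1), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(x[seg])]
  }, integer(1))
  onsets <- feet
  n_beats <- length(onsets) - 1L
  if (n_beats < 1) stop("fewer than 2 detectable beats")
  spans <- lapply(seq_len(n_beats), function(i) onsets[i]:(onsets[i + 1] - 1L))
  AC <- vapply(spans, function(s) max(x[s]) - min(x[s]), numeric(1))
  DC <- vapply(spans, function(s) mean(x[s]), numeric(1))
  pk <- peaks[peaks >= onsets[1] & peaks < onsets[length(onsets)]]
  structure(list(onsets = onsets, peaks = pk,
                 intervals = diff(onsets) / fs,
                 AC = AC, DC = DC, fs = fs), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, median interval %.3f s\n",
              length(x$intervals), median(x$intervals)))
  invisible(x)
}

#' Locate the dicrotic notch within one beat
#'
#' Searches the window (peak, peak + 0.6 x beat length) for the first local
#' minimum of the waveform; if none exists, falls back to the maximum of
#' the second difference (the strongest inflection) in that window.
#'
#' @param segment numeric samples of one beat (foot to foot).
#' @param peak_idx index of the systolic peak within `segment`.
#' @return Notch index within `segment`, or `NA` when no candidate exists.
#' @export
locate_notch <- function(segment, peak_idx) {
  n <- length(segment)
  hi <- min(n, peak_idx + floor(0.6 * n))
  if (hi - peak_idx < 3) return(NA_integer_)
  win <- segment[peak_idx:hi]
  m <- local_maxima(-win)  # local minima of the waveform
  if (length(m)) return(peak_idx + m[1] - 1L)
  d2 <- diff(win, differences = 2)
  if (length(d2) < 3 || max(d2) <= 0) return(NA_integer_)
  i <- which.max(d2)
  # a dicrotic wave shows as an interior curvature bump; a boundary
  # maximum is just monotone decay curvature, not an inflection
  if (i == 1 || i == length(d2)) return(NA_integer_)
  peak_idx + i
}

#' Morphological features of one beat
#'
#' The eight pulse-wave-analysis features: AC (peak-to-peak amplitude), DC
#' (beat mean), Area (mean of the min-max normalized waveform over the
#' normalized beat duration), NI (notch-to-systolic-peak ratio on the
#' foot-referenced waveform), and the mean/SD of the first-difference
#' slopes of the systolic upstroke (SPMEAN, SPVAR) and the diastolic
#' downstroke (DPMEAN, DPVAR), in amplitude units per second.
#'
#' @param segment numeric samples of one beat (foot to foot).
#' @param peak_idx index of the systolic peak within `segment`.
#' @param fs sampling rate (Hz), default 100.
#' @return A one-row data.frame `AC, DC, Area, NI, SPMEAN, SPVAR, DPMEAN,
#'   DPVAR` (NI is `NA` when no notch is found).
#' @export
beat_features <- function(segment, peak_idx, fs = 100) {
  n <- length(segment)
  stopifnot(n >= 4, peak_idx >= 1, peak_idx <= n)
  rng <- max(segment) - min(segment)
  norm <- if (rng > 0) (segment - min(segment)) / rng else segment * 0
  notch <- locate_notch(segment, peak_idx)
  foot_ref <- segment - segment[1]
  ni <- if (!is.na(notch) && foot_ref[peak_idx] != 0)
    foot_ref[notch] / foot_ref[peak_idx] else NA_real_
  up <- diff(segment[1:peak_idx]) * fs
  down <- if (peak_idx < n) diff(segment[peak_idx:n]) * fs else numeric(0)
  data.frame(
    AC = max(segment) - min(segment),
    DC = mean(segment),
    Area = mean(norm),
    NI = ni,
    SPMEAN = if (length(up)) mean(up) else NA_real_,
    SPVAR = if (length(up) > 1) sd(up) else 0,
    DPMEAN = if (length(down)) mean(down) else NA_real_,
    DPVAR = if (length(down) > 1) sd(down) else 0)
}

#' Per-beat morphological features of a trace
#'
#' Runs [detect_beats()] and [beat_features()] over a whole trace.
#'
#' @param trace a [signal_trace()] or numeric vector at `fs` Hz.
#' @param fs sampling rate (Hz).
#' @return data.frame, one row per beat: `beat`, `onset_s`, `interval_s`
#'   plus the eight features.
#' @export
trace_beat_features <- function(trace, fs = NULL) {
  beats <- detect_beats(trace, fs)
  x <- trace_values(trace)
  fs <- beats$fs
  n <- length(beats$intervals)
  rows <- lapply(seq_len(n), function(i) {
    i0 <- beats$onsets[i]
    i1 <- beats$onsets[i + 1] - 1L
    seg <- x[i0:i1]
    pk <- which.max(seg)
    cbind(data.frame(beat = i, onset_s = (i0 - 1) / fs,
                     interval_s = beats$intervals[i]),
          beat_features(seg, pk, fs))
  })
  do.call(rbind, rows)
}

#' Sliding-window medians of per-beat features
#'
#' One epoch per beat onset with a full window remaining; each epoch value
#' is the median of the feature over the beats whose onset falls in
#' `[t0, t0 + window)`.  Consecutive epochs advance by exactly one beat.
#'
#' @param features data.frame from [trace_beat_features()] (needs
#'   `onset_s`; all other numeric columns are aggregated).
#' @param window window length (s), default 20.
#' @param duration total recording duration (s); default: last onset +
#'   last interval.
#' @return data.frame, one row per epoch: `epoch_start_s`, `n_beats`, and
#'   the per-window medians of every feature column.
#' @export
window_median <- function(features, window = 20, duration = NULL) {
  stopifnot(is.data.frame(features), "onset_s" %in% names(features))
  if (is.null(duration))
    duration <- max(features$onset_s) +
      if ("interval_s" %in% names(features))
        features$interval_s[which.max(features$onset_s)] else 0
  if (duration < window) stop("recording shorter than one window")
  starts <- features$onset_s[features$onset_s + window <= duration + 1e-9]
  if (!length(starts)) stop("recording shorter than one window")
  cols <- setdiff(names(features), c("beat", "onset_s"))
  cols <- cols[vapply(features[cols], is.numeric, logical(1))]
  rows <- lapply(starts, function(t0) {
    inwin <- features$onset_s >= t0 - 1e-9 &
      features$onset_s < t0 + window - 1e-9
    med <- vapply(cols, function(cl)
      median(features[[cl]][inwin], na.rm = TRUE), numeric(1))
    cbind(data.frame(epoch_start_s = t0, n_beats = sum(inwin)),
          as.data.frame(as.list(med)))
  })
  do.call(rbind, rows)
}
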