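# Readers/writers and preprocessing. CSV dialect: comma, UTF-8, '.'
# decimal, mandatory header; missing values are empty fields.

#' Zero-phase low-pass filter
#'
#' Frequency-domain squared-magnitude Butterworth filter: the spectrum is
#' multiplied by \eqn{1 / (1 + (f/f_c)^{2n})}, exactly the zero-phase
#' amplitude response of a forward-backward (filtfilt) n-th order
#' Butterworth, so pulse morphology timing is preserved.  The signal is
#' reflection-padded to suppress circular edge effects.
#'
#' @param x numeric vector or [signal_trace()].
#' @param fs sampling rate (Hz).
#' @param fc cut-off frequency (Hz), default 10.
#' @param order filter order, default 4 (amplitude at `fc` is -6 dB, the
#'   filtfilt equivalent of a -3 dB one-pass design).
#' @return Filtered numeric vector (or `signal_trace` matching the input).
#' @export
lowpass_zero_phase <- function(x, fs, fc = 10, order = 4) {
  v <- trace_values(x)
  n <- length(v)
  pad <- min(n - 1, max(16, round(fs)))
  ext <- c(rev(v[2:(pad + 1)]), v, rev(v[(n - pad):(n - 1)]))
  m <- length(ext)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  H <- 1 / (1 + (abs(f) / fc)^(2 * order))
  out <- Re(fft(fft(ext) * H, inverse = TRUE)) / m
  out <- out[(pad + 1):(pad + n)]
  if (inherits(x, "signal_trace")) signal_trace(out, x$dt, x$unit) else out
}

# linear-interpolation resampling onto a uniform fs grid
resample_uniform <- function(t, x, fs) {
  grid <- seq(min(t), max(t), by = 1 / fs)
  approx(t, x, xout = grid, rule = 2)$y
}

#' Read a multi-channel recording
#'
#' Delimited text with a header, a `time_s` column and at least one signal
#' column (`ppg`, `bp`, `sv`, ...).  Channels are resampled to `fs` by
#' linear interpolation; `ppg` and `bp` are zero-phase low-pass filtered at
#' `lowpass_hz` (the `sv` channel is a per-beat step signal and is left
#' unfiltered).
#'
#' @param path file path.
#' @param fs target sampling rate (Hz), default 100.
#' @param lowpass_hz low-pass cut-off (Hz), default 10; `NA` disables.
#' @param subject_id optional id stored in the result (default: file stem).
#' @return A list of class `recording`: `subject_id`, `fs`, `time_s`, and
#'   one [signal_trace()] per signal column; `meta` records provenance.
#' @export
read_recording <- function(path, fs = 100, lowpass_hz = 10,
                           subject_id = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("missing required column: time_s")
  t <- df$time_s
  if (any(diff(t) <= 0)) stop("non-monotone time column")
  chans <- setdiff(names(df), "time_s")
  if (!length(chans)) stop("no signal columns besides time_s")
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  out <- list(subject_id = subject_id, fs = fs,
              time_s = seq(min(t), max(t), by = 1 / fs))
  units <- c(ppg = "a.u.", bp = "mmHg", sv = "mL")
  for (ch in chans) {
    v <- resample_uniform(t, df[[ch]], fs)
    if (!is.na(lowpass_hz) && ch %in% c("ppg", "bp"))
      v <- lowpass_zero_phase(v, fs, lowpass_hz)
    un <- if (ch %in% names(units)) units[[ch]] else "a.u."
    out[[ch]] <- signal_trace(v, 1 / fs, un)
  }
  out$meta <- list(source = path, lowpass_hz = lowpass_hz)
  class(out) <- "recording"
  out
}

#' @export
print.recording <- function(x, ...) {
  chans <- names(x)[vapply(x, inherits, logical(1), "signal_trace")]
  cat(sprintf("<recording> subject %s: %s; %d samples @ %g Hz\n",
              x$subject_id, paste(chans, collapse = ", "),
              length(x$time_s), x$fs))
  invisible(x)
}

#' Write an epoch feature table
#'
#' Stable column order, missing values as empty fields; round-trip safe via
#' [read_epochs()].
#'
#' @param table non-empty data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Write a simulation result as delimited text
#'
#' One row per sample: `time_s, p_p_mmHg, p_c_mmHg, q_mls, c1_ml_per_mmhg`
#' and `ppg_au` when the simulation carries a PPG trace.
#'
#' @param sim a `wk4_sim` result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "wk4_sim"))
  n <- length(sim$p_p$values)
  df <- data.frame(time_s = (seq_len(n) - 1) * sim$dt,
                   p_p_mmHg = sim$p_p$values,
                   p_c_mmHg = sim$p_c$values,
                   q_mls = sim$q$values,
                   c1_ml_per_mmhg = sim$c1_t$values)
  if (!is.null(sim$ppg)) df$ppg_au <- sim$ppg$values
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulation configuration file
#'
#' YAML or JSON with blocks `compliance: {Am, P0, P1, l}`,
#' `distal: {C2, R, L}`, `inflow: {CO or q0, T, Ts, alpha}` and
#' `sim: {dt, n_beats, warmup}`.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return list(`system` = [windkessel_system()], `sim` = list of
#'   simulation settings).
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (blk in c("compliance", "distal", "inflow"))
    if (is.null(cfg[[blk]])) stop("missing config block: ", blk)
  cp <- cfg$compliance
  profile <- compliance_profile(cp$Am, cp$P0, cp$P1,
                                l = if (is.null(cp$l)) 100 else cp$l)
  inf <- cfg$inflow
  T <- if (is.null(inf$T)) 0.8 else inf$T
  Ts <- if (is.null(inf$Ts)) 0.35 else inf$Ts
  alpha <- if (is.null(inf$alpha)) 1 / 3 else inf$alpha
  q0 <- if (!is.null(inf$q0)) inf$q0
  else if (!is.null(inf$CO)) q0_from_co(inf$CO, T, Ts, alpha)
  else stop("inflow block needs CO or q0")
  sys <- windkessel_system(profile, C2 = cfg$distal$C2, R = cfg$distal$R,
                           L = cfg$distal$L,
                           inflow = cardiac_inflow(q0, T, Ts, alpha))
  sim <- cfg$sim
  list(system = sys,
       sim = list(dt = if (is.null(sim$dt)) 0.01 else sim$dt,
                  n_beats = if (is.null(sim$n_beats)) 20 else sim$n_beats,
                  warmup = if (is.null(sim$warmup)) 10 else sim$warmup))
}
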