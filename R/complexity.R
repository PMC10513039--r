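#' Higuchi curve lengths
#'
#' For each time interval `k = 1..k_max` and each starting offset
#' `m = 1..k`, the curve length of the decimated series is
#' \deqn{L_m(k) = \frac{1}{k}\Big[\sum_{i=1}^{n_i} |x(m+ik)-x(m+(i-1)k)|\Big]
#' \frac{N-1}{n_i k}, \quad n_i = \lfloor (N-m)/k \rfloor,}
#' and the mean curve length is \eqn{L(k) = (1/k)\sum_{m=1}^{k} L_m(k)}
#' (the average over the k offsets, implemented exactly as printed).
#' For the linear ramp `x(i) = i` this gives `L(k) = (N-1)/k` exactly.
#'
#' @param x numeric series (length >= `2 * k_max + 1`, not constant).
#' @param k_max maximal interval, default 5.
#' @return A list of class `higuchi_result` with `k_values` and `L`.
#' @examples
#' higuchi_lengths(1:101)$L       # 100/k exactly
#' @export
higuchi_lengths <- function(x, k_max = 5) {
  x <- trace_values(x)
  N <- length(x)
  if (k_max < 2) stop("k_max must be >= 2")
  if (N < 2 * k_max + 1) stop("series too short for k_max")
  if (max(x) == min(x)) stop("constant series: curve length is zero")
  L <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      n_i <- (N - m) %/% k
      idx <- m + (0:n_i) * k
      s <- sum(abs(diff(x[idx])))
      (s * (N - 1) / (n_i * k)) / k
    }, numeric(1))
    sum(Lm) / k
  }, numeric(1))
  structure(list(k_values = seq_len(k_max), L = L),
            class = "higuchi_result")
}

#' Fit ln L against powers of ln(1/k)
#'
#' Ordinary least squares of `ln L(k)` on `ln(1/k)` (linear mode) or on its
#' first three powers (cubic mode).  Coefficient standard errors come from
#' the fit's variance-covariance matrix; note the cubic fit over the default
#' five abscissae is near-saturated (4 parameters, 1 residual degree of
#' freedom), so its standard errors are reported with that caveat.
#'
#' @param result a [higuchi_lengths()] result.
#' @param mode `"linear"` or `"cubic"`.
#' @return A list of class `loglog_fit`: `a0`, `a1`, `a2`, `a3` (zero in
#'   linear mode), `se_a0`, `se_a1`, `mode`, and the underlying `lm` fit.
#' @export
fit_loglog <- function(result, mode = c("linear", "cubic")) {
  stopifnot(inherits(result, "higuchi_result"))
  mode <- match.arg(mode)
  if (any(result$L <= 0)) stop("curve lengths must be positive")
  u <- log(1 / result$k_values)
  y <- log(result$L)
  need <- if (mode == "linear") 2 else 4
  if (length(u) < need) stop("not enough points for ", mode, " fit")
  fit <- if (mode == "linear") lm(y ~ u)
  else lm(y ~ u + I(u^2) + I(u^3))
  if (fit$qr$rank < need) stop("singular design in log-log fit")
  cf <- coef(fit)
  V <- suppressWarnings(vcov(fit))  # exact fits warn "essentially perfect"
  se <- sqrt(pmax(diag(V), 0))
  structure(list(
    a0 = unname(cf[1]), a1 = unname(cf[2]),
    a2 = if (mode == "cubic") unname(cf[3]) else 0,
    a3 = if (mode == "cubic") unname(cf[4]) else 0,
    se_a0 = unname(se[1]), se_a1 = unname(se[2]),
    mode = mode, fit = fit), class = "loglog_fit")
}

#' The three Higuchi complexity measures of a window
#'
#' `HFD_wave` is the slope a1 of the *linear* log-log fit on the 100-Hz
#' waveform; `HFD_DC` and `HFD_AC` are the intercepts a0 of *cubic* fits on
#' the per-beat baseline and pulsatile-amplitude series.  Each input series
#' is normalized by its window mean before the curve-length computation,
#' which makes all three measures invariant under amplitude scaling (the
#' slope is scale-invariant analytically; the intercepts shift by ln(scale)
#' on raw series).
#'
#' @param wave numeric 100-Hz waveform of the window (or [signal_trace()]).
#' @param dc_series,ac_series per-beat baseline and amplitude series of the
#'   window (from the beat-features module).
#' @param k_max maximal Higuchi interval, default 5.
#' @return A list: `HFD_wave`, `HFD_DC`, `HFD_AC` (a value is `NA` when its
#'   series is shorter than `2*k_max + 1` or constant), plus `se_a1_wave`
#'   and `se_a0_dc` from the fit covariance.
#' @export
hfd_measures <- function(wave, dc_series = NULL, ac_series = NULL,
                         k_max = 5) {
  norm <- function(x) {
    x <- trace_values(x)
    m <- mean(x)
    if (is.finite(m) && m != 0) x / m else x
  }
  wave_fit <- tryCatch(
    fit_loglog(higuchi_lengths(norm(wave), k_max), "linear"),
    error = function(e) NULL)
  cubic_a0 <- function(x) {
    if (is.null(x)) return(list(a0 = NA_real_, se = NA_real_))
    tryCatch({
      f <- fit_loglog(higuchi_lengths(norm(x), k_max), "cubic")
      list(a0 = f$a0, se = f$se_a0)
    }, error = function(e) list(a0 = NA_real_, se = NA_real_))
  }
  dc <- cubic_a0(dc_series)
  ac <- cubic_a0(ac_series)
  list(HFD_wave = if (is.null(wave_fit)) NA_real_ else wave_fit$a1,
       HFD_DC = dc$a0, HFD_AC = ac$a0,
       se_a1_wave = if (is.null(wave_fit)) NA_real_ else wave_fit$se_a1,
       se_a0_dc = dc$se)
}

#' Normalized autocorrelation function
#'
#' Mean-removed, biased-normalized estimator
#' \eqn{\rho(\tau) = \sum (x_t-\bar x)(x_{t+\tau}-\bar x) / \sum (x_t-\bar x)^2}
#' with \eqn{\rho(0) = 1} (the `stats::acf` default).
#'
#' @param x numeric series or [signal_trace()]; length > `max_lag`,
#'   positive variance.
#' @param max_lag maximal lag (samples).
#' @return A list of class `acf_result` with `lags` (0..max_lag) and `acf`.
#' @export
signal_acf <- function(x, max_lag) {
  x <- trace_values(x)
  if (length(x) <= max_lag) stop("series no longer than max_lag")
  if (sd(x) == 0) stop("zero-variance series")
  a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag, acf = drop(a$acf)),
            class = "acf_result")
}

#' Autocorrelation half-width
#'
#' Time at which the ACF first falls to 0.5, linearly interpolated between
#' the adjacent lags; `NA` when the ACF never reaches 0.5 within the
#' computed lags.
#'
#' @param result an [signal_acf()] result.
#' @param dt sample interval (s).
#' @return Half-width in seconds (`dt` x fractional lag), or `NA`.
#' @export
acf_halfwidth <- function(result, dt) {
  stopifnot(inherits(result, "acf_result"))
  a <- result$acf
  for (i in seq_len(length(a) - 1)) {
    if (a[i] >= 0.5 && a[i + 1] < 0.5) {
      frac <- (a[i] - 0.5) / (a[i] - a[i + 1])
      return((result$lags[i] + frac * (result$lags[i + 1] - result$lags[i])) * dt)
    }
  }
  NA_real_
}

#' Robust linear slope (IRLS, bisquare)
#'
#' Iteratively reweighted least squares with Tukey's bisquare weights
#' (`MASS::rlm`), as used for all slope/gradient analyses of complexity
#' measures against hemodynamic parameters.  The p-value is the Wald test
#' of the slope.
#'
#' @param x,y numeric vectors.
#' @return list(`slope`, `se`, `p`).
#' @export
robust_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0) return(list(slope = NA_real_,
                                               se = NA_real_, p = NA_real_))
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 50)
  s <- summary(fit)$coefficients
  tval <- s["x", "t value"]
  list(slope = unname(s["x", "Value"]), se = unname(s["x", "Std. Error"]),
       p = 2 * pt(-abs(tval), df = length(x) - 2))
}
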