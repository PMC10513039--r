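# Beat segmentation, notch location, per-beat morphology, epoch medians.

test_that("detector recovers the generator period on simulated PPG", {
  sim <- fig_sim()
  b <- detect_beats(sim$ppg)
  expect_equal(median(b$intervals), 0.80, tolerance = 0.0125)
  expect_true(all(diff(b$onsets) > 0))
  expect_true(all(b$AC >= 0))
})

test_that("pure sine: one beat per period, AC = 2x amplitude", {
  t <- seq(0, 12, by = 0.01)
  tr <- signal_trace(1 + 0.7 * sin(2 * pi * 1.25 * t), 0.01)
  b <- detect_beats(tr)
  expect_equal(median(b$intervals), 0.8, tolerance = 1e-9)
  expect_equal(median(b$AC), 1.4, tolerance = 1e-3)
  expect_equal(median(b$DC), 1, tolerance = 1e-2)
})

test_that("detection indices are invariant under amplitude scaling", {
  sim <- fig_sim()
  b1 <- detect_beats(sim$ppg)
  b2 <- detect_beats(signal_trace(sim$ppg$values * 1.2, 0.01))
  expect_identical(b1$onsets, b2$onsets)
  expect_identical(b1$peaks, b2$peaks)
  expect_equal(b2$AC, 1.2 * b1$AC, tolerance = 1e-12)
})

test_that("detector requires enough signal", {
  expect_error(detect_beats(signal_trace(rnorm(100), 0.01)), "3 s")
})

test_that("notch is found at the inter-Gaussian minimum, missing on monotone decay", {
  beat <- two_gauss_beat()
  pk <- which.max(beat)
  notch <- locate_notch(beat, pk)
  # brute-force oracle: global minimum strictly between the two bumps
  mid <- (which.max(beat) + 1):(which.max(beat[40:80]) + 39)
  expect_equal(notch, mid[which.min(beat[mid])])
  # pure decay has neither a minimum nor a positive inflection
  expect_true(is.na(locate_notch(exp(-seq(0, 3, length.out = 60)), 1)))
})

test_that("simulated beat has a notch with NI in (0, 1)", {
  sim <- fig_sim()
  feats <- trace_beat_features(sim$ppg)
  expect_true(all(feats$NI > 0 & feats$NI < 1, na.rm = TRUE))
  expect_true(any(is.finite(feats$NI)))
})

test_that("morphology features follow analytic values on synthetic beats", {
  # sawtooth: linear upstroke of slope s, SPVAR = 0
  fs <- 100
  up <- seq(0, 1, by = 0.02)
  down <- seq(1, 0.02, by = -0.0196)
  beat <- c(up, down)
  f <- beat_features(beat, which.max(beat), fs = fs)
  expect_equal(f$SPMEAN, 0.02 * fs, tolerance = 1e-9)
  expect_equal(f$SPVAR, 0, tolerance = 1e-9)
  expect_equal(f$AC, 1)
  # symmetric triangle: normalized area 0.5
  tri <- c(seq(0, 1, length.out = 41), seq(1, 0, length.out = 41)[-1])
  ft <- beat_features(tri, 41, fs = fs)
  expect_equal(ft$Area, 0.5, tolerance = 0.02)
  # scaling: AC, DC, slopes double; Area, NI unchanged
  b2 <- two_gauss_beat()
  f1 <- beat_features(b2, which.max(b2), fs)
  f2 <- beat_features(2 * b2, which.max(b2), fs)
  expect_equal(f2$AC, 2 * f1$AC)
  expect_equal(f2$DC, 2 * f1$DC)
  expect_equal(f2$SPMEAN, 2 * f1$SPMEAN)
  expect_equal(f2$Area, f1$Area)
  expect_equal(f2$NI, f1$NI)
})

test_that("window_median advances one beat and is outlier-robust", {
  onsets <- seq(0, 39.2, by = 0.8)
  feats <- data.frame(beat = seq_along(onsets), onset_s = onsets,
                      interval_s = 0.8, AC = 1, DC = 2)
  w <- window_median(feats, window = 20, duration = 40)
  # one window per beat start with >= 20 s remaining
  expect_equal(nrow(w), sum(onsets + 20 <= 40))
  expect_equal(w$epoch_start_s, onsets[onsets + 20 <= 40])
  expect_true(all(w$AC == 1) && all(w$DC == 2))
  # one outlier among 25 beats leaves the median unchanged
  feats$AC[10] <- 100
  w2 <- window_median(feats, window = 20, duration = 40)
  expect_true(all(w2$AC == 1))
  expect_error(window_median(feats[1:5, ], window = 20, duration = 4),
               "window")
})

test_that("features are invariant under time shift of the trace", {
  sim <- fig_sim()
  x <- sim$ppg$values
  shift <- 160  # two beats
  f1 <- trace_beat_features(x[(shift + 1):length(x)])
  f0 <- trace_beat_features(x)
  n <- min(nrow(f0) - 2, nrow(f1))
  cols <- c("AC", "DC", "Area", "NI", "SPMEAN", "SPVAR", "DPMEAN", "DPVAR")
  expect_equal(f1[1:n, cols], f0[3:(n + 2), cols], tolerance = 1e-6,
               ignore_attr = TRUE)
})
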