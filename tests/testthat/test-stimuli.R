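# Pulse and continuous stimulus protocols and response quantification.

test_that("bundled profile set is fixed, exemplars verbatim, ranges honored", {
  p <- langewouters_profiles()
  expect_equal(nrow(p), 45)
  expect_equal(unlist(p[1, c("Am", "P0", "P1")]),
               c(Am = 3.5, P0 = 50.4, P1 = 42.3))
  expect_equal(unlist(p[2, c("Am", "P0", "P1")]),
               c(Am = 6.18, P0 = -2.3, P1 = 21.6))
  expect_true(all(p$Am[-(1:2)] >= 3 & p$Am[-(1:2)] <= 7))
  expect_true(all(p$P0[-(1:2)] >= -10 & p$P0[-(1:2)] <= 60))
  expect_true(all(p$P1[-(1:2)] >= 15 & p$P1[-(1:2)] <= 45))
  # byte-identical across calls, caller's RNG stream untouched
  set.seed(99)
  before <- .Random.seed
  expect_identical(p, langewouters_profiles())
  expect_identical(before, .Random.seed)
})

test_that("sv pulse perturbs exactly one beat's q0", {
  sys <- fig_system()
  pert <- make_sv_pulse(sys, pulse_stimulus("sv", magnitude = 0.2,
                                            onset = 5), n_beats = 10)
  q0s <- vapply(pert$inflow, `[[`, numeric(1), "q0")
  q0 <- sys$inflow[[1]]$q0
  expect_equal(q0s[5], 1.2 * q0)
  expect_equal(q0s[-5], rep(q0, 9))
  # SV is linear in q0
  expect_equal(stroke_volume(pert$inflow[[5]]),
               1.2 * stroke_volume(sys$inflow[[1]]))
  expect_error(make_sv_pulse(sys, pulse_stimulus("sv", onset = 11),
                             n_beats = 10), "out of range")
})

test_that("zero-magnitude stimulus produces identically zero distortion", {
  sys <- fig_system()
  tr <- pv_spec_from_profile(aorta1())
  base <- simulate_wk4(sys, n_beats = 8, transfer = tr)
  pert <- simulate_wk4(make_sv_pulse(sys, pulse_stimulus("sv", magnitude = 0),
                                     n_beats = 8), transfer = tr)
  m <- response_metrics(pert, base)
  expect_identical(max(abs(m$distortion$values)), 0)
  expect_identical(m$OS, 0)
  expect_true(is.na(m$HW))
})

test_that("sv-pulse response peaks near onset and decays; mini is ~volume-ratio smaller", {
  sys <- fig_system()
  tr <- pv_spec_from_profile(aorta1())
  base <- simulate_wk4(sys, n_beats = 20, transfer = tr)
  sv <- response_metrics(
    simulate_wk4(make_sv_pulse(sys, n_beats = 20), transfer = tr), base)
  # positive peak within 2 beats of the onset beat (10), decaying after
  peak_beat <- which.max(sv$envelope$peak)
  expect_true(abs(peak_beat - 10) <= 2)
  after <- sv$envelope$peak[peak_beat:20]
  expect_true(all(diff(after) < 0))
  expect_gt(sv$OS, 0)
  expect_gt(sv$HW, 0)
  mini <- response_metrics(
    simulate_wk4(make_mini_pulse(sys, n_beats = 20), transfer = tr), base)
  expect_lt(mini$OS / sv$OS, 0.1)  # much smaller response
  # mini distortion is more pronounced in the PPG first derivative
  d <- function(x) diff(x)
  rel_deriv <- max(abs(d(mini$distortion$values))) /
    max(abs(d(base$ppg$values)))
  rel_raw <- mini$OS / diff(range(base$ppg$values))
  expect_gt(rel_deriv / rel_raw, 1)
})

test_that("mini pulse in diastole warns and has negligible effect", {
  sys <- fig_system()
  tr <- pv_spec_from_profile(aorta1())
  base <- simulate_wk4(sys, n_beats = 8, transfer = tr)
  expect_warning(
    pert_sys <- make_mini_pulse(sys, pulse_stimulus("mini", onset = 4.5),
                                n_beats = 8),
    "diastole")
  m <- response_metrics(simulate_wk4(pert_sys, transfer = tr), base)
  expect_lt(m$OS, 1e-12)
})

test_that("overshoot grows with sv-pulse magnitude", {
  sys <- fig_system()
  tr <- pv_spec_from_profile(aorta1())
  base <- simulate_wk4(sys, n_beats = 12, transfer = tr)
  os <- vapply(c(0.05, 0.15, 0.3), function(mag) {
    p <- simulate_wk4(make_sv_pulse(sys, pulse_stimulus("sv", mag),
                                    n_beats = 12), transfer = tr)
    response_metrics(p, base)$OS
  }, numeric(1))
  expect_true(all(diff(os) > 0))
})

test_that("random stimuli honor the uniform white-noise protocol", {
  spec <- random_stimulus_spec(5.95, 1.4, seed = 4)
  s1 <- make_random_stimuli(spec)
  expect_equal(nrow(s1), 20)
  expect_identical(s1, make_random_stimuli(spec))  # determinism
  # zero half-width -> constant at (shifted) baseline
  s0 <- make_random_stimuli(random_stimulus_spec(5.95, 1.4,
                                                 noise_halfwidth = 0,
                                                 baseline_shift = 0.1,
                                                 seed = 1))
  expect_equal(s0$co, rep(5.95 * 1.1, 20))
  expect_equal(s0$r, rep(1.4 * 1.1, 20))
  # empirical SD -> halfwidth/sqrt(3) = 2.89% for large n
  big <- make_random_stimuli(random_stimulus_spec(1, 1, n_beats = 2e5,
                                                  seed = 8))
  expect_equal(sd(big$co), 0.05 / sqrt(3), tolerance = 0.02)
  expect_lt(abs(mean(big$co) - 1), 5e-4)
})

test_that("envelope half-width of a triangular envelope is half its base", {
  t <- seq(0, 10, by = 0.5)
  h <- 2
  b <- 6
  peak <- pmax(0, h * (1 - abs(t - 5) / (b / 2)))
  expect_equal(wkppg:::envelope_halfwidth(t, peak), b / 2, tolerance = 1e-9)
})

test_that("sweep grid has the protocol shape and flags out-of-band rows", {
  tab <- sweep_grid(profiles = langewouters_profiles()[c(1, 2, 12), ],
                    n_beats = 12)
  expect_equal(nrow(tab), 3 * 4 * 3)
  expect_true(all(is.na(tab$error)))
  # discarded iff SBP outside [80, 220]
  expect_equal(tab$discarded, tab$SBP > 220 | tab$SBP < 80)
  expect_true(any(tab$discarded) && any(!tab$discarded))
  # conservation at every retained grid point
  ok <- !tab$discarded
  expect_true(all(abs(tab$MAP[ok] - tab$R[ok] * tab$CO[ok] * 1000 / 60) /
                    (tab$R[ok] * tab$CO[ok] * 1000 / 60) < 0.01))
})
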