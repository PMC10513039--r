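# Core model: compliance law, ejection waveform, simulation contracts.

test_that("compliance_c1 matches the arctangent-derivative law", {
  a1 <- compliance_profile(3.5, 50.4, 42.3, l = 1)
  # maximum at p = P0, value Am / (pi * P1)
  expect_equal(compliance_c1(a1, 50.4), 3.5 / (pi * 42.3), tolerance = 1e-12)
  # half maximum one steepness-pressure away
  expect_equal(compliance_c1(a1, 50.4 + 42.3),
               compliance_c1(a1, 50.4) / 2, tolerance = 1e-12)
  # independent evaluation for the second exemplar at 100 mmHg
  a2 <- compliance_profile(6.18, -2.3, 21.6, l = 1)
  expect_equal(compliance_c1(a2, 100),
               6.18 / (pi * 21.6 * (1 + ((100 + 2.3) / 21.6)^2)),
               tolerance = 1e-12)
  expect_equal(round(compliance_c1(a2, 100), 5), 0.00389)
  # symmetry about P0 and positivity
  x <- seq(0, 120, by = 7)
  expect_equal(compliance_c1(a1, 50.4 + x), compliance_c1(a1, 50.4 - x))
  expect_true(all(compliance_c1(a1, seq(-50, 300, by = 10)) > 0))
  # linear in l
  expect_equal(compliance_c1(compliance_profile(3.5, 50.4, 42.3, l = 100), 80),
               100 * compliance_c1(a1, 80))
  expect_error(compliance_c1(a1, NaN), "finite")
})

test_that("inflow waveform is continuous, zero-terminated, and integrates to SV", {
  inf <- cardiac_inflow(q0 = 356.1, T = 0.8, Ts = 0.35, alpha = 1 / 3)
  aTs <- 0.35 / 3
  # continuity at the peak-time knot; peak value q0
  expect_equal(inflow_value(inf, aTs), 356.1, tolerance = 1e-12)
  expect_equal(inflow_value(inf, aTs - 1e-9), inflow_value(inf, aTs + 1e-9),
               tolerance = 1e-6)
  # analytic zero at Ts (cos argument = pi/2), zero in diastole
  expect_equal(inflow_value(inf, 0.35), 0, tolerance = 1e-12)
  expect_equal(inflow_value(inf, c(0.5, 0.79)), c(0, 0))
  expect_error(inflow_value(inf, -0.01), "outside")
  expect_error(inflow_value(inf, 0.81), "outside")
  # closed-form SV = 2 q0 Ts / pi for alpha = 1/3, against quadrature
  sv_quad <- integrate(function(t) inflow_value(inf, t), 0, 0.8,
                       subdivisions = 1000, rel.tol = 1e-10)$value
  expect_equal(stroke_volume(inf), 2 * 356.1 * 0.35 / pi, tolerance = 1e-12)
  expect_equal(stroke_volume(inf), sv_quad, tolerance = 1e-8)
  expect_equal(stroke_volume(inf), 79.33, tolerance = 1e-3)
})

test_that("q0_from_co inverts the stroke-volume integral", {
  expect_equal(q0_from_co(5.95, 0.8, 0.35), 356.05, tolerance = 1e-4)
  expect_equal(q0_from_co(0, 0.8, 0.35), 0)
  # round-trip within 0.1% for general alpha (numeric quadrature oracle)
  for (alpha in c(1 / 3, 0.25, 0.5)) {
    q0 <- q0_from_co(5.0, 0.9, 0.3, alpha)
    inf <- cardiac_inflow(q0, 0.9, 0.3, alpha)
    sv <- integrate(function(t) inflow_value(inf, t), 0, 0.9,
                    subdivisions = 1000, rel.tol = 1e-10)$value
    expect_equal(sv * 60 / 0.9 / 1000, 5.0, tolerance = 1e-3)
  }
})

test_that("simulation reaches flow-conservation steady state", {
  sim <- fig_sim()
  # mean p_p = R * CO (138.83 mmHg) within 1%
  expect_equal(mean(sim$p_p$values), 1.4 * 5.95 * 1000 / 60,
               tolerance = 0.01)
  # SV measured on the simulated inflow trace within 0.5%
  sv_trace <- sum(sim$q_in$values) * sim$dt / length(sim$beat_starts)
  expect_equal(sv_trace, stroke_volume(cardiac_inflow(q0_from_co(5.95))),
               tolerance = 5e-3)
  # instantaneous compliance positive everywhere, traces equal length
  expect_true(all(sim$c1_t$values > 0))
  expect_equal(length(sim$p_c$values), length(sim$p_p$values))
  expect_true(sim$sbp_ok)
})

test_that("zero inflow decays monotonically (passive discharge)", {
  sys <- windkessel_system(aorta1(), C2 = 0.1, R = 1.4, L = 0.03,
                           inflow = cardiac_inflow(0))
  sim <- simulate_wk4(sys, n_beats = 15, warmup_beats = 1)
  pp <- sim$p_p$values
  # passive discharge toward 0 with time constant ~ R (C1 + C2); a small
  # L-C ripple rides on the decay, so per-beat means are compared
  expect_true(all(pp <= 80 + 1e-6))
  means <- vapply(seq_along(sim$beat_starts), function(i) {
    j <- c(sim$beat_starts, length(pp) + 1L)
    mean(pp[j[i]:(j[i + 1] - 1L)])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_lt(pp[length(pp)], 0.2 * 80)
  expect_false(sim$sbp_ok)  # SBP < 80 mmHg is flagged
})

test_that("first-order and third-order formulations agree within 0.5 mmHg", {
  sys <- fig_system()
  a <- simulate_wk4(sys, n_beats = 6)
  b <- simulate_wk4(sys, n_beats = 6, formulation = "third_order")
  expect_lt(max(abs(a$p_p$values - b$p_p$values)), 0.5)
  # also with per-beat varying R and CO
  st <- make_random_stimuli(random_stimulus_spec(5.95, 1.4, n_beats = 6,
                                                 seed = 9))
  sys2 <- system_from_stimuli(aorta1(), st)
  a2 <- simulate_wk4(sys2)
  b2 <- simulate_wk4(sys2, formulation = "third_order")
  expect_lt(max(abs(a2$p_p$values - b2$p_p$values)), 0.5)
})

test_that("halving dt changes the steady-state trace by < 0.1 mmHg", {
  sys <- fig_system()
  a <- simulate_wk4(sys, n_beats = 5)
  b <- simulate_wk4(sys, n_beats = 5, dt = 0.005)
  sub <- b$p_p$values[seq(1, length(b$p_p$values), by = 2)]
  expect_lt(max(abs(sub - a$p_p$values)), 0.1)
})

test_that("pv_transfer is a monotone arctangent map with affine gain", {
  tr <- pv_spec(Am_v = 3.5, P0_v = 50.4, P1_v = 42.3, gain = 1, offset = 0.2)
  p <- seq(40, 200, by = 5)
  v <- pv_transfer(p, tr)
  expect_true(all(diff(v) > 0))
  # midpoint at P0_v
  expect_equal(pv_transfer(50.4, tr), 3.5 / 2 + 0.2, tolerance = 1e-12)
  # constant pressure -> constant PPG
  expect_equal(sd(pv_transfer(rep(100, 10), tr)), 0)
  # doubled gain doubles pulsatile amplitude, leaves shape unchanged
  tr2 <- pv_spec(3.5, 50.4, 42.3, gain = 2, offset = 0.2)
  v2 <- pv_transfer(p, tr2)
  expect_equal(diff(range(v2)), 2 * diff(range(v)), tolerance = 1e-12)
  n1 <- (v - min(v)) / diff(range(v))
  n2 <- (v2 - min(v2)) / diff(range(v2))
  expect_equal(n1, n2, tolerance = 1e-12)
  # signal_trace in, signal_trace out
  out <- pv_transfer(signal_trace(p, 0.01, "mmHg"), tr)
  expect_s3_class(out, "signal_trace")
  expect_equal(out$unit, "a.u.")
})

test_that("constructors validate their invariants", {
  expect_error(compliance_profile(-1, 0, 10), "Am")
  expect_error(compliance_profile(1, 0, -10), "P1")
  expect_error(cardiac_inflow(100, T = 0.8, Ts = 0.9), "Ts < T")
  expect_error(cardiac_inflow(-5), ">= 0")
  expect_error(windkessel_system(aorta1(), C2 = 0.1, R = -1, L = 0.03,
                                 inflow = cardiac_inflow(100)), "R")
  expect_error(signal_trace(c(1, NA), 0.01), "finite")
  expect_error(signal_trace(1:3, dt = 0), "dt")
  expect_error(pv_spec(1, 0, 10, gain = 0), "gain")
})
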