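# Shared fixtures: the flagship simulation scenario (Aorta1 profile,
# T = 0.8 s, Ts = 0.35 s, alpha = 1/3, CO = 5.95 L/min, C2 = 0.1, R = 1.4,
# L = 0.03) and small helpers. All fixtures are built in code.

aorta1 <- function(l = 100) compliance_profile(3.5, 50.4, 42.3, l = l)
aorta2 <- function(l = 100) compliance_profile(6.18, -2.3, 21.6, l = l)

fig_system <- function(R = 1.4, CO = 5.95, C2 = 0.1, L = 0.03,
                       T = 0.8, Ts = 0.35, alpha = 1 / 3, l = 100) {
  windkessel_system(aorta1(l), C2 = C2, R = R, L = L,
                    inflow = cardiac_inflow(q0_from_co(CO, T, Ts, alpha),
                                            T, Ts, alpha))
}

# memoised baseline run of the flagship scenario (20 beats, with PPG)
fig_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- fig_system()
      cache <<- simulate_wk4(sys, n_beats = 20,
                             transfer = pv_spec_from_profile(aorta1()))
    }
    cache
  }
})

# two-Gaussian synthetic beat: systolic wave + dicrotic wave
two_gauss_beat <- function(n = 80, a2 = 0.35, mu1 = 0.25, mu2 = 0.55,
                           s1 = 0.07, s2 = 0.09) {
  t <- seq(0, 1, length.out = n)
  exp(-(t - mu1)^2 / (2 * s1^2)) + a2 * exp(-(t - mu2)^2 / (2 * s2^2))
}
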