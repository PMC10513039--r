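# Higuchi curve lengths, log-log fits, ACF and half-width.

test_that("Higuchi lengths are exact on the linear ramp", {
  h <- higuchi_lengths(1:101, k_max = 5)
  expect_equal(h$L, 100 / (1:5), tolerance = 1e-12)
  f <- fit_loglog(h, "linear")
  expect_equal(f$a1, 1, tolerance = 1e-9)
  expect_equal(f$a0, log(100), tolerance = 1e-9)
  expect_lt(f$se_a0, 1e-9)
  expect_lt(f$se_a1, 1e-9)
})

test_that("curve length is homogeneous of degree one", {
  set.seed(3)
  x <- cumsum(rnorm(400))
  h1 <- higuchi_lengths(x)
  h2 <- higuchi_lengths(2 * x)
  expect_equal(h2$L, 2 * h1$L, tolerance = 1e-12)
  expect_error(higuchi_lengths(rep(1, 50)), "constant")
  expect_error(higuchi_lengths(1:5, k_max = 5), "short")
})

test_that("cubic fit recovers exact cubic coefficients", {
  u <- log(1 / (1:5))
  L <- exp(1.3 + 2 * u - 0.4 * u^2 + 0.07 * u^3)
  h <- structure(list(k_values = 1:5, L = L), class = "higuchi_result")
  f <- fit_loglog(h, "cubic")
  expect_equal(c(f$a0, f$a1, f$a2, f$a3), c(1.3, 2, -0.4, 0.07),
               tolerance = 1e-8)
  # linear mode on the same points reports a2 = a3 = 0
  fl <- fit_loglog(h, "linear")
  expect_identical(c(fl$a2, fl$a3), c(0, 0))
})

test_that("white noise has Higuchi dimension 2", {
  set.seed(11)
  slopes <- replicate(50, fit_loglog(higuchi_lengths(rnorm(1e4)),
                                     "linear")$a1)
  expect_equal(mean(slopes), 2, tolerance = 0.05)
})

test_that("hfd_measures are invariant under amplitude scaling", {
  set.seed(21)
  wave <- 1 + 0.3 * sin(seq(0, 40 * pi, length.out = 2000)) + rnorm(2000, 0, 0.02)
  dc <- 1 + cumsum(rnorm(25, 0, 0.01))
  ac <- 0.5 + cumsum(rnorm(25, 0, 0.005))
  a <- hfd_measures(wave, dc, ac)
  b <- hfd_measures(1.2 * wave, 1.2 * dc, 1.2 * ac)
  expect_equal(a$HFD_wave, b$HFD_wave, tolerance = 1e-10)
  expect_equal(a$HFD_DC, b$HFD_DC, tolerance = 1e-10)
  expect_equal(a$HFD_AC, b$HFD_AC, tolerance = 1e-10)
  # short or constant per-beat series -> missing, flagged
  expect_true(is.na(hfd_measures(wave, dc_series = rep(1, 25))$HFD_DC))
  expect_true(is.na(hfd_measures(wave, dc_series = dc[1:8])$HFD_DC))
})

test_that("rougher per-beat series have larger HFD intercept", {
  # white noise vs AR(1) phi = 0.9 at matched marginal variance
  set.seed(31)
  d <- replicate(40, {
    wn <- 1 + rnorm(30, 0, 0.02)
    ar <- 1 + 0.02 * as.numeric(arima.sim(list(ar = 0.9), 30)) * sqrt(1 - 0.81)
    hfd_measures(NULL, dc_series = wn)$HFD_DC -
      hfd_measures(NULL, dc_series = ar)$HFD_DC
  })
  expect_gt(mean(d), 0)
  expect_gt(mean(d > 0), 0.8)
})

test_that("ACF estimator is normalized and affine-invariant", {
  set.seed(41)
  x <- rnorm(500)
  a <- signal_acf(x, 20)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf) <= 1))
  b <- signal_acf(3 * x + 7, 20)
  expect_equal(a$acf, b$acf, tolerance = 1e-12)
  expect_error(signal_acf(rep(2, 100), 10), "variance")
  # AR(1) phi = 0.9: acf(tau) ~ 0.9^tau
  set.seed(42)
  y <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  ay <- signal_acf(y, 10)
  expect_equal(ay$acf[2:11], 0.9^(1:10), tolerance = 0.03)
})

test_that("ACF half-width interpolates the 0.5 crossing", {
  # analytic AR(1) ACF: crossing between lags 6 and 7 at 6.59
  a <- structure(list(lags = 0:10, acf = 0.9^(0:10)), class = "acf_result")
  expect_equal(acf_halfwidth(a, 1), 6.5916, tolerance = 1e-4)
  expect_equal(acf_halfwidth(a, 0.01), 0.065916, tolerance = 1e-4)
  # never reaching 0.5 -> missing
  flat <- structure(list(lags = 0:5, acf = c(1, rep(0.9, 5))),
                    class = "acf_result")
  expect_true(is.na(acf_halfwidth(flat, 1)))
  # white noise drops below 0.5 at lag 1
  set.seed(5)
  w <- signal_acf(rnorm(1e4), 10)
  expect_lte(acf_halfwidth(w, 0.01), 0.01)
})

test_that("robust slope matches the generating slope with outliers present", {
  set.seed(51)
  x <- runif(200)
  y <- 2 + 3 * x + rnorm(200, 0, 0.1)
  y[1:10] <- y[1:10] + 5  # gross outliers
  rs <- robust_slope(x, y)
  expect_equal(rs$slope, 3, tolerance = 0.05)
  expect_lt(rs$p, 1e-6)
})
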