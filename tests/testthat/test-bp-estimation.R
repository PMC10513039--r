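# Feature assembly and the evaluation harness.

make_small_table <- function() {
  spec <- cohort_spec(n_subjects = 3, duration = 80, seed = 17)
  coh <- suppressMessages(make_cohort(spec))
  co_fluctuation_split(build_feature_matrix(coh))
}

tab_cache <- make_small_table()

test_that("feature matrix has the contract columns and epoch counts", {
  tab <- tab_cache
  need <- c("subject_id", "epoch_start_s", "AC", "DC", "Area", "NI",
            "SPMEAN", "SPVAR", "DPMEAN", "DPVAR", "HRV", "HFD_wave",
            "HFD_DC", "HFD_AC", "ACF_HW", "MAP", "PP", "SBP", "DBP",
            "co_fluct", "temporal_ok", "stratum")
  expect_true(all(need %in% names(tab)))
  expect_equal(sort(unique(tab$subject_id)), c("S001", "S002", "S003"))
  # ~ one epoch per beat with 20 s remaining: (80 - 20) / T beats
  per_subj <- table(tab$subject_id)
  expect_true(all(per_subj > 55 & per_subj < 95))
  expect_true(all(is.finite(tab$MAP)))
})

test_that("CO-fluctuation split is a pooled-median split and rank-invariant", {
  tab <- tab_cache
  thr <- median(tab$co_fluct)
  expect_identical(tab$stratum == "high", tab$co_fluct > thr)
  expect_lte(abs(sum(tab$stratum == "high") - sum(tab$stratum == "low")), 1)
  t2 <- tab
  t2$co_fluct <- 2 * t2$co_fluct
  expect_identical(co_fluctuation_split(t2)$stratum, tab$stratum)
  # all-equal co_fluct -> everything "low"
  t3 <- tab
  t3$co_fluct <- 1
  expect_true(all(co_fluctuation_split(t3)$stratum == "low"))
})

test_that("per-feature correlations behave on engineered columns", {
  tab <- tab_cache
  set.seed(1)
  tab$proxy <- tab$MAP + rnorm(nrow(tab), 0, 0.1)
  tab$noise <- rnorm(nrow(tab))
  fc <- feature_bp_correlation(tab, features = c("proxy", "noise"))
  expect_gt(fc$r_low[1], 0.99)
  expect_gt(fc$r_high[1], 0.99)
  expect_lt(max(abs(fc[2, c("r_low", "r_high")])), 0.15)
  # identical strata give a non-significant difference
  dup <- tab
  dup$stratum <- factor(rep(c("low", "high"), length.out = nrow(dup)),
                        levels = c("low", "high"))
  dup$MAPcopy <- dup$MAP
  fd <- feature_bp_correlation(dup, features = "DC")
  expect_gt(fd$p_diff, 0.05)
})

test_that("LOSO linear regression is exact on linear ground truth and never leaks", {
  tab <- tab_cache
  # construct a noiseless linear target from two features
  tab$target_lin <- 3 + 2 * tab$AC - 5 * tab$HRV
  tab$MAPsave <- tab$MAP
  tab$MAP <- tab$target_lin
  r <- linreg_eval(tab, "morph+hrv", target = "MAP")
  expect_true(all(r$r > 0.999, na.rm = TRUE))
  expect_true(all(r$MAE < 1e-6, na.rm = TRUE))
  expect_s3_class(r, "eval_report")
  expect_equal(nrow(r), 2)
})

test_that("bnn pipeline is deterministic, calibrated, and fits linear truth", {
  tab <- tab_cache
  tab$MAP <- 3 + 2 * scale(tab$AC)[, 1] - 1 * scale(tab$HRV)[, 1]
  r1 <- bnn_eval(tab, "morph+hrv", seed = 5)
  r2 <- bnn_eval(tab, "morph+hrv", seed = 5)
  expect_identical(r1, r2)
  # capacity suffices: near-perfect fit (r is diluted in the stratum with
  # little target variance, so the error magnitude is asserted too)
  expect_true(all(r1$r > 0.9, na.rm = TRUE))
  expect_true(all(r1$MAE < 0.2, na.rm = TRUE))
  # scoring excludes the 10 calibration epochs of each subject
  expect_lte(sum(r1$n_epochs),
             nrow(tab) - 10 * length(unique(tab$subject_id)))
})

test_that("label-shuffled targets carry no information through the bnn", {
  tab <- tab_cache
  set.seed(31)
  rs <- vapply(1:5, function(i) {
    t2 <- tab
    t2$MAP <- sample(t2$MAP)
    r <- bnn_eval(t2, "morph+hrv", seed = i)
    mean(r$r, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rs, na.rm = TRUE), 0.35)
})

test_that("easy-ensemble subsets balance the target bins", {
  set.seed(4)
  y <- c(rnorm(500, 0), rnorm(20, 6))  # strongly imbalanced
  subs <- wkppg:::easy_ensemble_subsets(y, bins = 5, n_ensemble = 10)
  expect_equal(length(subs), 10)
  br <- seq(min(y), max(y), length.out = 6)
  full <- table(cut(y, br, include.lowest = TRUE))
  for (s in subs[1:3]) {
    cnt <- table(cut(y[s], br, include.lowest = TRUE))
    # over-represented bins are cut down to the smallest occupied bin
    expect_lte(max(cnt), max(5, min(full[full > 0])))
    expect_lt(length(s), length(y) / 2)
  }
})

test_that("sensitivity map recovers engineered partial gradients", {
  set.seed(8)
  n <- 2000
  d <- data.frame(CO = runif(n, 4, 6), R = runif(n, 0.7, 1.3),
                  C1 = runif(n, 0.2, 1))
  d$f_co <- d$CO
  d$f_noise <- rnorm(n)
  m <- sensitivity_map(d, "f_co")
  expect_equal(m$gradients$CO$slope, 1, tolerance = 0.05)
  expect_lt(abs(m$gradients$R$slope), 0.05)
  expect_lt(abs(m$gradients$C1$slope), 0.05)
  mn <- sensitivity_map(d, "f_noise")
  expect_gt(mn$gradients$CO$p, 0.01)
  expect_true(all(m$bins$count >= 5))
})
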