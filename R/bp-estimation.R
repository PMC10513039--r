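# Epoch feature assembly and the feature -> blood-pressure evaluation
# harness: per-feature correlations with Fisher-z stratum comparison,
# leave-one-subject-out (LOSO) multiple linear regression, and a
# Bayesian-regularized single-hidden-layer network with EasyEnsemble-style
# target balancing; plus binned distribution/sensitivity maps.

MORPH_FEATURES <- c("AC", "DC", "Area", "NI", "SPMEAN", "SPVAR",
                    "DPMEAN", "DPVAR")
TEMPORAL_FEATURES <- c("HFD_wave", "HFD_DC", "HFD_AC", "ACF_HW")

#' Per-epoch feature matrix of one recording
#'
#' Beats are detected on the PPG channel; the eight morphological features
#' are median-aggregated per 20-s epoch (one epoch per beat with a full
#' window remaining); the temporal features (HFD_wave, HFD_DC, HFD_AC,
#' ACF_HW), HRV (SDNN of the beat intervals) and the reference BP summary
#' (MAP, PP, SBP, DBP from the BP channel) are computed per epoch; the
#' CO-fluctuation index is the epoch mean of |delta CO| over consecutive
#' beats (CO per beat = SV x 60 / interval).
#'
#' @param recording list with `signal_trace`s `ppg`, `bp`, `sv` (a
#'   `recording` object or a data.frame with those columns at 100 Hz).
#' @param subject_id id attached to the rows.
#' @param window epoch length (s), default 20.
#' @return data.frame, one row per epoch.
#' @export
epoch_features <- function(recording, subject_id = "S000", window = 20) {
  if (is.data.frame(recording)) {
    fs <- 1 / median(diff(recording$time_s))
    ppg <- recording$ppg; bp <- recording$bp; sv <- recording$sv
  } else {
    fs <- recording$fs
    ppg <- trace_values(recording$ppg)
    bp <- trace_values(recording$bp)
    sv <- trace_values(recording$sv)
    subject_id <- recording$subject_id
  }
  beats <- detect_beats(ppg, fs = fs)
  feats <- trace_beat_features(ppg, fs = fs)
  nb <- nrow(feats)
  onsets <- beats$onsets
  # per-beat reference quantities on the same beat grid
  per_beat <- lapply(seq_len(nb), function(i) {
    s <- onsets[i]:(onsets[i + 1] - 1L)
    svb <- median(sv[s])
    data.frame(sbp_b = max(bp[s]), dbp_b = min(bp[s]), map_b = mean(bp[s]),
               sv_b = svb, co_b = svb * 60 / (length(s) / fs) / 1000)
  })
  per_beat <- do.call(rbind, per_beat)
  feats <- cbind(feats, per_beat)
  duration <- length(ppg) / fs
  starts <- feats$onset_s[feats$onset_s + window <= duration + 1e-9]
  if (!length(starts)) stop("recording shorter than one epoch window")
  rows <- lapply(starts, function(t0) {
    inwin <- which(feats$onset_s >= t0 - 1e-9 &
                     feats$onset_s < t0 + window - 1e-9)
    f <- feats[inwin, ]
    med <- vapply(MORPH_FEATURES, function(cl) median(f[[cl]], na.rm = TRUE),
                  numeric(1))
    i0 <- onsets[inwin[1]]
    i1 <- min(i0 + round(window * fs) - 1L, length(ppg))
    hfd <- hfd_measures(ppg[i0:i1] / mean(ppg[i0:i1]),
                        dc_series = f$DC, ac_series = f$AC)
    acf_hw <- tryCatch(acf_halfwidth(signal_acf(ppg[i0:i1],
                                                max_lag = round(5 * fs)),
                                     1 / fs),
                       error = function(e) NA_real_)
    data.frame(subject_id = subject_id, epoch_start_s = t0,
               n_beats = length(inwin), t(med),
               HRV = sd(f$interval_s),
               HFD_wave = hfd$HFD_wave, HFD_DC = hfd$HFD_DC,
               HFD_AC = hfd$HFD_AC, ACF_HW = acf_hw,
               se_a0_dc = hfd$se_a0_dc, se_a1_wave = hfd$se_a1_wave,
               MAP = mean(f$map_b), PP = mean(f$sbp_b - f$dbp_b),
               SBP = median(f$sbp_b), DBP = median(f$dbp_b),
               co_fluct = mean(abs(diff(f$co_b))))
  })
  do.call(rbind, rows)
}

#' Assemble the cohort feature table
#'
#' Runs [epoch_features()] over every recording of a cohort; rows missing
#' any temporal feature are flagged (`temporal_ok`).
#'
#' @param cohort a `wkppg_cohort` (or named list of recordings).
#' @param window epoch length (s), default 20.
#' @return data.frame of class `feature_table`.
#' @export
build_feature_matrix <- function(cohort, window = 20) {
  recs <- if (inherits(cohort, "wkppg_cohort")) cohort$recordings else cohort
  tabs <- lapply(names(recs), function(id)
    epoch_features(recs[[id]], subject_id = id, window = window))
  out <- do.call(rbind, tabs)
  out$temporal_ok <- complete.cases(out[, TEMPORAL_FEATURES])
  class(out) <- c("feature_table", class(out))
  out
}

#' Split epochs by cardiac-output fluctuation
#'
#' Threshold = pooled median of `co_fluct` across all epochs; above ->
#' `"high"`, at-or-below -> `"low"` (ties go low).  Rank-invariant.
#'
#' @param table a feature table with `co_fluct`.
#' @return The table with a `stratum` factor column added.
#' @export
co_fluctuation_split <- function(table) {
  stopifnot("co_fluct" %in% names(table))
  thr <- median(table$co_fluct, na.rm = TRUE)
  table$stratum <- factor(ifelse(table$co_fluct > thr, "high", "low"),
                          levels = c("low", "high"))
  table
}

# Fisher z comparison of two independent correlations
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (any(!is.finite(c(r1, r2))) || n1 < 4 || n2 < 4) return(NA_real_)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z))
}

#' Per-feature correlation with BP, by CO-fluctuation stratum
#'
#' Pearson r of every feature against the reference (`MAP` or `PP`) within
#' each stratum, with a Fisher-z test of the high-vs-low difference
#' (independent strata).
#'
#' @param table a stratified feature table (see [co_fluctuation_split()]).
#' @param features feature columns (default morphology + HRV + temporal).
#' @param target `"MAP"` or `"PP"`.
#' @return data.frame: `feature`, `r_low`, `r_high`, `n_low`, `n_high`,
#'   `p_diff`.
#' @export
feature_bp_correlation <- function(table,
                                   features = c(MORPH_FEATURES, "HRV",
                                                TEMPORAL_FEATURES),
                                   target = "MAP") {
  stopifnot("stratum" %in% names(table), target %in% names(table))
  rows <- lapply(features, function(f) {
    rs <- lapply(c("low", "high"), function(st) {
      d <- table[table$stratum == st, ]
      ok <- is.finite(d[[f]]) & is.finite(d[[target]])
      if (sum(ok) < 10 || sd(d[[f]][ok]) == 0)
        return(list(r = NA_real_, n = sum(ok)))
      list(r = cor(d[[f]][ok], d[[target]][ok]), n = sum(ok))
    })
    data.frame(feature = f, r_low = rs[[1]]$r, r_high = rs[[2]]$r,
               n_low = rs[[1]]$n, n_high = rs[[2]]$n,
               p_diff = fisher_z_diff(rs[[1]]$r, rs[[1]]$n,
                                      rs[[2]]$r, rs[[2]]$n))
  })
  do.call(rbind, rows)
}

# named feature sets of the evaluation protocol
feature_set_columns <- function(feature_set) {
  switch(feature_set,
         morph = MORPH_FEATURES,
         `morph+hrv` = c(MORPH_FEATURES, "HRV"),
         `morph+hrv+complexity` = c(MORPH_FEATURES, "HRV",
                                    TEMPORAL_FEATURES),
         complexity = TEMPORAL_FEATURES,
         stop("unknown feature set: ", feature_set))
}

loso_folds <- function(table) {
  ids <- unique(table$subject_id)
  lapply(ids, function(id) list(test_id = id,
                                train = which(table$subject_id != id),
                                test = which(table$subject_id == id)))
}

eval_report <- function(table, pred, feature_set, scored) {
  out <- lapply(c("low", "high"), function(st) {
    i <- scored & !is.na(table$stratum) & table$stratum == st &
      is.finite(pred)
    if (sum(i) < 3)
      return(data.frame(stratum = st, feature_set = feature_set,
                        r = NA_real_, MAE = NA_real_, n_epochs = sum(i)))
    err <- pred[i] - table$target[i]
    data.frame(stratum = st, feature_set = feature_set,
               r = if (sd(pred[i]) > 0) cor(pred[i], table$target[i])
                   else NA_real_,
               MAE = median(abs(err)), n_epochs = sum(i))
  })
  do.call(rbind, out)
}

#' LOSO multiple linear regression evaluation
#'
#' Ordinary least squares on the training subjects (collinear columns
#' dropped with a warning), predictions for the held-out subject, pooled
#' over folds; r (Pearson, prediction vs reference) and MAE (median
#' absolute error) per CO-fluctuation stratum.
#'
#' @param table stratified feature table.
#' @param feature_set `"morph"`, `"morph+hrv"`, `"morph+hrv+complexity"` or
#'   `"complexity"`.
#' @param target `"MAP"` or `"PP"`.
#' @return data.frame of class `eval_report` (one row per stratum).
#' @export
linreg_eval <- function(table, feature_set = "morph+hrv+complexity",
                        target = "MAP") {
  stopifnot("stratum" %in% names(table))
  cols <- feature_set_columns(feature_set)
  ok <- complete.cases(table[, c(cols, target)])
  table$target <- table[[target]]
  pred <- rep(NA_real_, nrow(table))
  for (fold in loso_folds(table)) {
    tr <- intersect(fold$train, which(ok))
    te <- intersect(fold$test, which(ok))
    if (length(tr) < length(cols) + 2 || !length(te)) next
    X <- table[tr, cols, drop = FALSE]
    keep <- vapply(X, function(v) sd(v) > 0, logical(1))
    d <- cbind(target = table$target[tr], X[, keep, drop = FALSE])
    fit <- lm(target ~ ., data = d)
    if (any(is.na(coef(fit)))) {
      drop_cols <- names(coef(fit))[is.na(coef(fit))]
      warning("dropping collinear columns: ",
              paste(drop_cols, collapse = ", "))
      keep_cols <- setdiff(names(d)[-1], sub("`(.*)`", "\\1", drop_cols))
      fit <- lm(target ~ ., data = d[, c("target", keep_cols)])
    }
    pred[te] <- predict(fit, table[te, , drop = FALSE])
  }
  rep_ <- eval_report(table, pred, feature_set, scored = ok)
  class(rep_) <- c("eval_report", class(rep_))
  rep_
}

#' LOSO Bayesian-regularized network evaluation
#'
#' Per held-out subject: (1) the training targets are cut into
#' `bins` equal-count bins and `n_ensemble` balanced subsets are built by
#' undersampling the over-represented bins (EasyEnsemble adapted to
#' regression); (2) one single-hidden-layer network (`hidden` tanh units,
#' weight decay set by the evidence approximation) is trained per subset
#' and predictions are ensemble-averaged; (3) a linear calibration
#' (gain + offset) is fitted on the held-out subject's first 10 epochs and
#' those epochs are excluded from scoring; (4) r and MAE are reported per
#' CO-fluctuation stratum.  Deterministic given `seed`.
#'
#' @inheritParams linreg_eval
#' @param hidden hidden units, default 15.
#' @param n_ensemble ensemble members, default 10.
#' @param bins target bins for balancing, default 5.
#' @param n_calib calibration epochs, default 10.
#' @param seed RNG seed, default 1.
#' @return data.frame of class `eval_report`.
#' @export
bnn_eval <- function(table, feature_set = "morph+hrv+complexity",
                     target = "MAP", hidden = 15, n_ensemble = 10,
                     bins = 5, n_calib = 10, seed = 1L) {
  stopifnot("stratum" %in% names(table))
  set.seed(seed)
  cols <- feature_set_columns(feature_set)
  ok <- complete.cases(table[, c(cols, target)])
  table$target <- table[[target]]
  pred <- rep(NA_real_, nrow(table))
  scored <- rep(FALSE, nrow(table))
  for (fold in loso_folds(table)) {
    tr <- intersect(fold$train, which(ok))
    te <- intersect(fold$test, which(ok))
    if (length(tr) < 30 || length(te) < 3) next
    X <- as.matrix(table[tr, cols, drop = FALSE])
    y <- table$target[tr]
    subsets <- easy_ensemble_subsets(y, bins, n_ensemble)
    nets <- lapply(subsets, function(idx)
      brnn_train(X[idx, , drop = FALSE], y[idx], hidden = hidden))
    Xte <- as.matrix(table[te, cols, drop = FALSE])
    p <- rowMeans(vapply(nets, function(net) brnn_predict(net, Xte),
                         numeric(nrow(Xte))))
    # chronological calibration on the first n_calib epochs
    ord <- order(table$epoch_start_s[te])
    if (length(te) > n_calib) {
      ci <- ord[seq_len(n_calib)]
      si <- ord[-seq_len(n_calib)]
      cf <- if (sd(p[ci]) > 0) coef(lm(table$target[te][ci] ~ p[ci]))
            else c(mean(table$target[te][ci]), 0)
      pred[te[si]] <- cf[1] + cf[2] * p[si]
      scored[te[si]] <- TRUE
    } else {
      warning("fewer than ", n_calib + 1,
              " test epochs: calibration skipped for ", fold$test_id)
      pred[te] <- p
      scored[te] <- TRUE
    }
  }
  rep_ <- eval_report(table, pred, feature_set, scored = scored)
  class(rep_) <- c("eval_report", class(rep_))
  rep_
}

# equal-width target bins over the BP range; each subset undersamples the
# over-represented bins to the smallest non-empty bin count (floored at 5),
# giving balanced, diverse ensemble training sets.  (Equal-count bins would
# make undersampling vacuous.)
easy_ensemble_subsets <- function(y, bins, n_ensemble) {
  br <- seq(min(y), max(y), length.out = bins + 1)
  bin <- cut(y, breaks = br, include.lowest = TRUE)
  counts <- table(bin)
  n_min <- max(5, min(counts[counts > 0]))
  lapply(seq_len(n_ensemble), function(b) {
    unlist(lapply(levels(bin), function(lv) {
      idx <- which(bin == lv)
      if (length(idx) <= n_min) idx else sample(idx, n_min)
    }), use.names = FALSE)
  })
}

#' Binned distribution and sensitivity map of a feature
#'
#' Bins the epochs on three hemodynamic axes (default CO, R, C1), reports
#' the per-bin mean feature and count (bins with fewer than `min_count`
#' epochs are dropped), and estimates the partial gradient of the feature
#' along each axis by robust linear fits within slices of the other two
#' axes (count-weighted average of the slice slopes).
#'
#' @param table feature table augmented with the axis columns.
#' @param feature feature column name.
#' @param axes axis column names, default `c("CO", "R", "C1")`.
#' @param n_bins bins per axis, default `c(8, 6, 6)`.
#' @param min_count minimum epochs per retained bin, default 5.
#' @return list of class `sensitivity_map`: `bins` (data.frame with bin
#'   centers, mean feature, count) and `gradients` (named per-axis partial
#'   slopes with p-values).
#' @export
sensitivity_map <- function(table, feature, axes = c("CO", "R", "C1"),
                            n_bins = c(8, 6, 6), min_count = 5) {
  stopifnot(feature %in% names(table), all(axes %in% names(table)))
  ok <- complete.cases(table[, c(feature, axes)])
  d <- table[ok, ]
  n_bins <- rep_len(n_bins, length(axes))
  bin_idx <- mapply(function(ax, nb) {
    br <- seq(min(d[[ax]]), max(d[[ax]]), length.out = nb + 1)
    pmin(pmax(findInterval(d[[ax]], br, rightmost.closed = TRUE), 1), nb)
  }, axes, n_bins, SIMPLIFY = FALSE)
  key <- do.call(paste, c(bin_idx, sep = ":"))
  agg <- lapply(split(seq_len(nrow(d)), key), function(i) {
    row <- lapply(seq_along(axes), function(a) mean(d[[axes[a]]][i]))
    names(row) <- axes
    cbind(as.data.frame(row), value = mean(d[[feature]][i]),
          count = length(i))
  })
  bins <- do.call(rbind, agg)
  bins <- bins[bins$count >= min_count, , drop = FALSE]
  gradients <- lapply(seq_along(axes), function(a) {
    others <- setdiff(seq_along(axes), a)
    slice_key <- do.call(paste, c(bin_idx[others], sep = ":"))
    slopes <- lapply(split(seq_len(nrow(d)), slice_key), function(i) {
      if (length(i) < max(min_count, 4)) return(NULL)
      rs <- robust_slope(d[[axes[a]]][i], d[[feature]][i])
      if (!is.finite(rs$slope)) return(NULL)
      c(slope = rs$slope, w = length(i))
    })
    slopes <- do.call(rbind, slopes)
    if (is.null(slopes) || !nrow(slopes))
      return(list(slope = NA_real_, p = NA_real_))
    sl <- sum(slopes[, "slope"] * slopes[, "w"]) / sum(slopes[, "w"])
    # pooled significance: robust fit on the full partialled data
    rs_all <- robust_slope(d[[axes[a]]], d[[feature]])
    list(slope = sl, p = rs_all$p)
  })
  names(gradients) <- axes
  structure(list(bins = bins, gradients = gradients, feature = feature),
            class = "sensitivity_map")
}
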