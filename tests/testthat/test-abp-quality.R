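test_that("onset detector finds one onset per cycle on clean ABP", {
  # 75 bpm, 60 s
  cfg <- simulation_config(duration_s = 310, rr_mean_ms = 800,
                           rr_lf_amp_ms = 0, rr_hf_amp_ms = 0,
                           rr_noise_sd_ms = 0, seed = 2)
  out <- render_record(cfg)
  idx60 <- seq_len(60 * 125)
  onsets <- detect_abp_onsets(out$record$abp[idx60], 125)
  expect_gte(length(onsets), 74)
  expect_lte(length(onsets), 76)
  expect_true(all(diff(onsets) > 0))
  # within 2 samples of ground-truth cycle starts on the full record
  onsets_full <- detect_abp_onsets(out$record$abp, 125)
  err <- vapply((onsets_full - 1) / 125, function(t0)
    min(abs(t0 - out$truth$ecg_beat_times_s)), numeric(1))
  expect_lte(max(err) * 125, 2)
})

test_that("onset detector errors on flat signal", {
  expect_error(detect_abp_onsets(rep(100, 125 * 10), 125), "no cycles")
})

test_that("cycle SQIs are finite, fixed-width, and flag flat-lines", {
  out <- clean_record(seed = 5, rr_noise_sd_ms = 4)
  onsets <- detect_abp_onsets(out$record$abp, 125)
  feats <- compute_cycle_sqis(out$record$abp, onsets, 125)
  sqi_cols <- c("pulse_pressure", "duration_s", "mean_abs_diff",
                "skewness", "n_local_max", "clip_fraction")
  expect_true(all(is.finite(as.matrix(feats[, sqi_cols]))))
  expect_equal(nrow(feats), length(onsets) - 1)
  # clean periodic cycles: small dispersion of the feature vectors
  z <- scale(as.matrix(feats[, sqi_cols]))
  z[, attr(z, "scaled:scale") == 0] <- 0
  # flat-lined cycle has zero pulse pressure
  flat <- inject_artifacts(out$record, 0,
                           at = data.frame(kind = "flatline",
                                           start_s = 50.2, len_s = 1.5))
  onsets_f <- detect_abp_onsets(flat$abp, 125)
  feats_f <- compute_cycle_sqis(flat$abp, onsets_f, 125)
  in_flat <- feats_f$onset_sample / 125 > 50.2 &
    feats_f$next_onset_sample / 125 < 51.7
  if (any(in_flat)) {
    expect_true(all(feats_f$pulse_pressure[in_flat] < 1))
  }
  # the cycle spanning the flat-line stands far from the clean population
  span <- feats_f$next_onset_sample / 125 - feats_f$onset_sample / 125
  expect_gt(max(span), 1.2 * stats::median(span))
})

test_that("clustering labels the corrupted minority PQ and the clean majority GQ", {
  out <- clean_record(seed = 9, rr_noise_sd_ms = 4)
  bt <- out$truth$ecg_beat_times_s
  sel <- round(seq(20, length(bt) - 10, length.out = 10))
  rec <- inject_artifacts(out$record, 0,
                          at = data.frame(kind = "spike",
                                          start_s = bt[sel] + 0.15,
                                          len_s = 0.12))
  onsets <- detect_abp_onsets(rec$abp, 125)
  feats <- cluster_quality(compute_cycle_sqis(rec$abp, onsets, 125), seed = 1)
  corrupted <- vapply(seq_len(nrow(feats)), function(k) {
    s0 <- (feats$onset_sample[k] - 1) / 125
    s1 <- (feats$next_onset_sample[k] - 1) / 125
    any(rec$artifact_log$start_s < s1 & rec$artifact_log$end_s > s0)
  }, logical(1))
  expect_gte(sum(feats$quality[corrupted] == "PQ"), 9)
  expect_equal(unique(feats$quality[!corrupted]), "GQ")
})

test_that("identical cycles collapse to a single all-GQ cluster", {
  out <- clean_record(seed = 3)  # zero modulation: identical cycles
  onsets <- detect_abp_onsets(out$record$abp, 125)
  feats <- cluster_quality(compute_cycle_sqis(out$record$abp, onsets, 125))
  expect_true(all(feats$quality == "GQ"))
})

test_that("the larger k-means cluster is labelled GQ", {
  # two well-separated feature blobs, 60 vs 40: majority must be GQ even
  # though the minority blob has the larger pulse pressure
  set.seed(4)
  f60 <- matrix(rnorm(60 * 6, 0, 0.05), ncol = 6)
  f40 <- matrix(rnorm(40 * 6, 0, 0.05), ncol = 6)
  f40[, 1] <- f40[, 1] + 60   # far away in pulse pressure
  mat <- rbind(f60, f40)
  mat[, 1] <- mat[, 1] + 35; mat[, 2] <- mat[, 2] + 0.8
  feats <- data.frame(cycle_index = 1:100, onset_sample = 1:100,
                      next_onset_sample = 2:101)
  feats[, c("pulse_pressure", "duration_s", "mean_abs_diff", "skewness",
            "n_local_max", "clip_fraction")] <- mat
  feats$quality <- "unassigned"
  class(feats) <- c("cycle_features", "data.frame")
  labelled <- cluster_quality(feats, seed = 1)
  expect_equal(sum(labelled$quality == "GQ"), 60)
  expect_true(all(labelled$quality[1:60] == "GQ"))
})

test_that("R_GQ is the percentage of good cycles and matches a recount", {
  expect_equal(compute_rgq(8, 2), 80)
  expect_equal(compute_rgq(5, 0), 100)
  expect_equal(compute_rgq(79, 21), 79)
  expect_error(compute_rgq(0, 0), "no cycles")
  # brute-force recount oracle over randomized label vectors
  set.seed(7)
  for (i in 1:20) {
    labels <- sample(c("GQ", "PQ"), 50, replace = TRUE)
    expect_equal(compute_rgq(sum(labels == "GQ"), sum(labels == "PQ")),
                 100 * mean(labels == "GQ"))
  }
})

test_that("records shorter than 5 minutes are rejected before rating", {
  cfg <- simulation_config(duration_s = 200, seed = 2)
  out <- render_record(cfg)
  rep <- filter_record(out$record)
  expect_false(rep$accepted)
  expect_equal(rep$reason, "too short")
  expect_true(is.na(rep$r_gq))
})

test_that("clean record passes with R_GQ exactly 100", {
  out <- clean_record(seed = 5, rr_noise_sd_ms = 4)
  rep <- filter_record(out$record, seed = 1)
  expect_true(rep$accepted)
  expect_equal(rep$r_gq, 100)
})

test_that("quarter corruption drives R_GQ below the 80 percent gate", {
  out <- clean_record(seed = 6, rr_noise_sd_ms = 4)
  bt <- out$truth$ecg_beat_times_s
  sel <- round(seq(3, length(bt) - 2,
                   length.out = ceiling(0.26 * (length(bt) - 1))))
  rec <- inject_artifacts(out$record, 0,
                          at = data.frame(kind = "spike",
                                          start_s = bt[sel] + 0.15,
                                          len_s = 0.12))
  expect_gte(corrupted_cycle_fraction(rec), 0.25)
  rep <- filter_record(rec, seed = 1)
  expect_false(rep$accepted)
  expect_lt(rep$r_gq, 80)
})

test_that("R_GQ decreases as more cycles are corrupted, decision stable across seeds", {
  out <- clean_record(seed = 8, rr_noise_sd_ms = 4)
  bt <- out$truth$ecg_beat_times_s
  rgq <- vapply(c(8, 4, 2), function(every) {
    sel <- seq(3, length(bt) - 2, by = every)
    rec <- inject_artifacts(out$record, 0,
                            at = data.frame(kind = "spike",
                                            start_s = bt[sel] + 0.15,
                                            len_s = 0.12))
    filter_record(rec, seed = 1)$r_gq
  }, numeric(1))
  expect_true(all(diff(rgq) < 0))
  expect_true(all(rgq >= 0 & rgq <= 100))
  # reseeded clustering does not flip the decision on well-separated cases
  sel <- seq(3, length(bt) - 2, by = 4)
  rec <- inject_artifacts(out$record, 0,
                          at = data.frame(kind = "spike",
                                          start_s = bt[sel] + 0.15,
                                          len_s = 0.12))
  decisions <- vapply(1:10, function(s) filter_record(rec, seed = s)$accepted,
                      logical(1))
  expect_true(all(!decisions))
  clean_decisions <- vapply(1:10, function(s)
    filter_record(out$record, seed = s)$accepted, logical(1))
  expect_true(all(clean_decisions))
})
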