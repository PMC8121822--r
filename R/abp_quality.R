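#' Detect ABP cycle onsets
#'
#' Slope-sum-function style detector: the windowed sum of positive slopes is
#' thresholded adaptively, each threshold crossing is traced back to the
#' preceding pressure minimum (the cycle foot), and a 0.27 s refractory
#' period enforces the physiological 25-220 bpm band.
#'
#' @param abp numeric ABP waveform.
#' @param fs sampling rate (Hz).
#' @return strictly increasing integer vector of onset sample indices.
#' @export
detect_abp_onsets <- function(abp, fs) {
  stopifnot(fs > 0)
  if (length(abp) < 2 * fs) stop("need at least 2 s of ABP", call. = FALSE)
  d <- pmax(diff(abp), 0)
  w <- max(3L, round(0.128 * fs))
  ssf <- as.numeric(stats::filter(d, rep(1, w), sides = 1))
  ssf[is.na(ssf)] <- 0
  # median of the positive slope-sum mass: robust to artifact-inflated tails
  thr <- 0.5 * stats::median(ssf[ssf > 0])
  if (!is.finite(thr) || thr <= 0) stop("no cycles detected", call. = FALSE)
  cross <- which(ssf[-1] >= thr & ssf[-length(ssf)] < thr) + 1L
  onsets <- integer(0)
  min_gap <- round(0.27 * fs)
  back <- round(0.25 * fs)
  for (c0 in cross) {
    lo <- max(1L, c0 - back)
    onset <- lo + which.min(abp[lo:c0]) - 1L
    if (!length(onsets) || onset - onsets[length(onsets)] >= min_gap) {
      onsets <- c(onsets, onset)
    }
  }
  if (length(onsets) < 2) stop("no cycles detected", call. = FALSE)
  onsets
}

#' Per-cycle signal quality features of an ABP record
#'
#' Computes, for every cardiac cycle `[onset, next onset)`, a fixed vector
#' of signal quality indices: pulse pressure (max - min), cycle duration
#' (s), mean absolute first difference, skewness, number of local maxima,
#' and fraction of samples at the clip rails. Together these separate
#' flat-lines, spikes, saturation and double beats from clean pulses.
#'
#' @param abp numeric ABP waveform.
#' @param onsets onset indices from [detect_abp_onsets()].
#' @param fs sampling rate (Hz).
#' @return data.frame of class `cycle_features`: `cycle_index`,
#'   `onset_sample`, `next_onset_sample`, one column per SQI, and a
#'   `quality` column (`"unassigned"` until clustered).
#' @export
compute_cycle_sqis <- function(abp, onsets, fs) {
  stopifnot(length(onsets) >= 2)
  n_cyc <- length(onsets) - 1L
  rails <- range(abp)
  feat <- t(vapply(seq_len(n_cyc), function(k) {
    seg <- abp[onsets[k]:(onsets[k + 1] - 1L)]
    if (length(seg) < 3) return(rep(NA_real_, 6))
    dseg <- diff(seg)
    c(pulse_pressure = max(seg) - min(seg),
      duration_s = length(seg) / fs,
      mean_abs_diff = mean(abs(dseg)),
      skewness = if (stats::sd(seg) > 0) e1071::skewness(seg) else 0,
      n_local_max = sum(dseg[-length(dseg)] > 0 & dseg[-1] <= 0),
      clip_fraction = mean(seg <= rails[1] + 1e-9 | seg >= rails[2] - 1e-9))
  }, numeric(6)))
  out <- data.frame(cycle_index = seq_len(n_cyc),
                    onset_sample = onsets[-length(onsets)],
                    next_onset_sample = onsets[-1])
  out <- cbind(out, as.data.frame(feat))
  out$quality <- ifelse(rowSums(is.na(feat)) > 0, "PQ", "unassigned")
  for (j in colnames(feat)) out[[j]][is.na(out[[j]])] <- 0
  class(out) <- c("cycle_features", "data.frame")
  out
}

sqi_feature_names <- c("pulse_pressure", "duration_s", "mean_abs_diff",
                       "skewness", "n_local_max", "clip_fraction")

# robust per-record standardization of the SQI matrix: deviations from the
# per-feature median in units of max(MAD, physiological floor), so a clean
# majority defines the reference and artifact cycles land many units away
# regardless of how homogeneous the record is
sqi_floors <- c(pulse_pressure = 1, duration_s = 0.05, mean_abs_diff = 0.5,
                skewness = 0.25, n_local_max = 1, clip_fraction = 0.05)
# amplitude-scaled features (pulse pressure, slope magnitude) legitimately
# track blood-pressure state; a wider relative floor keeps within-record
# state contrast from masquerading as a quality split
sqi_rel_floors <- c(pulse_pressure = 0.15, duration_s = 0.05,
                    mean_abs_diff = 0.15, skewness = 0.05,
                    n_local_max = 0.05, clip_fraction = 0.05)

robust_scale_sqis <- function(x) {
  med <- apply(x, 2, stats::median)
  sc <- pmax(apply(x, 2, stats::mad), sqi_floors[colnames(x)],
             sqi_rel_floors[colnames(x)] * abs(med))
  sweep(sweep(x, 2, med), 2, sc, "/")
}

#' Cluster ABP cycles into good- and poor-quality groups
#'
#' K-means with k = 2 on robustly standardized SQI features (per-feature
#' median/MAD with physiological scale floors); since most cycles of a
#' usable record are expected to be clean, the larger cluster is labelled
#' good quality (GQ). An equal-size tie goes to the cluster whose centroid
#' has the larger (unscaled) pulse pressure. When no cycle deviates
#' substantially from the record median (every robust deviation norm below
#' 8) there is no poor-quality subpopulation to find: the clustering is
#' degenerate and every cycle is labelled GQ.
#'
#' @param features a `cycle_features` data.frame.
#' @param seed RNG seed for the k-means restarts.
#' @return the same data.frame with `quality` set to `"GQ"` or `"PQ"`.
#' @export
cluster_quality <- function(features, seed = 1L) {
  stopifnot(inherits(features, "cycle_features"))
  idx <- which(features$quality != "PQ")   # short cycles pre-flagged PQ
  if (length(idx) < 2) stop("need at least 2 clusterable cycles", call. = FALSE)
  x <- as.matrix(features[idx, sqi_feature_names])
  z <- robust_scale_sqis(x)
  norms <- sqrt(rowSums(z^2))
  if (max(norms) < 8) {
    features$quality[idx] <- "GQ"
    return(features)
  }
  rng <- local_rng(substream_seed(seed, "cluster"))
  on.exit(rng())
  km <- stats::kmeans(z, centers = 2, nstart = 10)
  sizes <- tabulate(km$cluster, 2)
  gq <- if (sizes[1] != sizes[2]) {
    which.max(sizes)
  } else {
    # tie: clean ABP has substantial pulse pressure
    which.max(tapply(x[, "pulse_pressure"], km$cluster, mean))
  }
  features$quality[idx] <- ifelse(km$cluster == gq, "GQ", "PQ")
  features
}

#' Good-quality cycle ratio
#'
#' The acceptance ratio of the ABP quality gate:
#' `R_GQ = 100 * n_GQ / (n_GQ + n_PQ)` (percent).
#'
#' @param n_gq number of good-quality cycles.
#' @param n_pq number of poor-quality cycles.
#' @return percentage in `[0, 100]`.
#' @export
compute_rgq <- function(n_gq, n_pq) {
  if (n_gq + n_pq <= 0) stop("no cycles to rate", call. = FALSE)
  100 * n_gq / (n_gq + n_pq)
}

#' Run the full ABP quality gate on a record
#'
#' Records shorter than 5 minutes are rejected outright. Otherwise the
#' chain onset detection -> per-cycle SQIs -> k-means GQ/PQ clustering ->
#' R_GQ is run and the record is accepted when R_GQ is at least `min_rgq`
#' percent.
#'
#' @param record a `waveform_record`.
#' @param seed RNG seed for clustering.
#' @param min_rgq acceptance threshold in percent (default 80).
#' @return a `quality_report`: `accepted`, `reason`, `r_gq`, `n_gq`,
#'   `n_pq`, `per_cycle`.
#' @export
filter_record <- function(record, seed = 1L, min_rgq = 80) {
  stopifnot(inherits(record, "waveform_record"))
  dur <- length(record$t_s) / record$fs
  if (dur < 300) {
    return(structure(list(accepted = FALSE, reason = "too short",
                          r_gq = NA_real_, n_gq = NA_integer_,
                          n_pq = NA_integer_, per_cycle = NULL),
                     class = "quality_report"))
  }
  onsets <- detect_abp_onsets(record$abp, record$fs)
  feats <- compute_cycle_sqis(record$abp, onsets, record$fs)
  feats <- cluster_quality(feats, seed = seed)
  n_gq <- sum(feats$quality == "GQ")
  n_pq <- sum(feats$quality == "PQ")
  r_gq <- compute_rgq(n_gq, n_pq)
  structure(list(accepted = r_gq >= min_rgq,
                 reason = if (r_gq >= min_rgq) "accepted" else "low quality",
                 r_gq = r_gq, n_gq = n_gq, n_pq = n_pq, per_cycle = feats),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  if (is.na(x$r_gq)) {
    cat(sprintf("quality_report: rejected (%s)\n", x$reason))
  } else {
    cat(sprintf("quality_report: %s, R_GQ = %.1f%% (%d GQ / %d PQ cycles)\n",
                if (x$accepted) "accepted" else "rejected",
                x$r_gq, x$n_gq, x$n_pq))
  }
  invisible(x)
}

#' Serialize a quality report to JSON
#'
#' @param report a `quality_report`.
#' @param path output path.
#' @export
write_quality_report <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
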