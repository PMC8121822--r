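#' Cut a record into fixed-length overlapping segments
#'
#' Windows start at 0 and advance by `length_s - overlap_s` (290 s with the
#' defaults, i.e. consecutive 5-min windows share 10 s); a final partial
#' window is discarded. All three channels are cut identically.
#'
#' @param record a `waveform_record`.
#' @param length_s window length in seconds (default 300).
#' @param overlap_s overlap between consecutive windows (default 10).
#' @return list of `waveform_record` segments, each with an `offset_s`
#'   element; empty list (with a warning) when the record is shorter than
#'   one window.
#' @export
segment_signals <- function(record, length_s = 300, overlap_s = 10) {
  stopifnot(inherits(record, "waveform_record"), length_s > overlap_s,
            overlap_s >= 0)
  dur <- length(record$t_s) / record$fs
  if (dur < length_s) {
    warning("record shorter than one segment window")
    return(list())
  }
  stride <- length_s - overlap_s
  starts <- seq(0, dur - length_s, by = stride)
  lapply(starts, function(s0) {
    idx <- which(record$t_s >= s0 & record$t_s < s0 + length_s)
    structure(list(t_s = record$t_s[idx] - s0, ecg = record$ecg[idx],
                   ppg = record$ppg[idx], abp = record$abp[idx],
                   fs = record$fs, source = record$source,
                   artifact_log = record$artifact_log, offset_s = s0),
              class = "waveform_record")
  })
}

#' Simulate a heterogeneous cohort of synthetic records
#'
#' Draws one record per subject with ICU-like between-subject spread,
#' scaled to the depressed and strongly right-skewed variability typical of
#' critically ill adults (cohort RMSSD ~ 10 +/- 6 ms, SDNN ~ 13 +/- 10 ms):
#' mean RR uniform 700-1000 ms; LF modulation (0.095 Hz), HF modulation
#' (0.25 Hz) and white RR jitter log-normally distributed between subjects
#' (medians 11, 3.5 and 2.2 ms); mean PTT 200-300 ms and beat-to-beat PTT
#' jitter drawn from `ptt_jitter_range_ms`. Records cycle
#' through sustained hypotensive (85/55 mmHg), normotensive (120/80) and
#' hypertensive (150/95) schedules so each state is represented.
#'
#' @param n number of records.
#' @param seed cohort seed; record i uses a seed derived from it.
#' @param duration_s record duration (default 310 s, one 5-min segment).
#' @param ptt_jitter_range_ms range of the per-record PTT jitter SD
#'   (default `c(5, 10)` ms).
#' @param artifact_rate ABP artifacts per minute (default 0).
#' @return list of `list(record =, truth =, config =)` entries.
#' @export
simulate_cohort <- function(n, seed = 1L, duration_s = 310,
                            ptt_jitter_range_ms = c(5, 10),
                            artifact_rate = 0) {
  states <- list(hypotension = c(85, 55),
                 normotension = c(120, 80),
                 hypertension = c(150, 95))
  rng <- local_rng(substream_seed(seed, "rr"))
  on.exit(rng())
  rln <- function(med, gsd, lo, hi) {
    pmin(pmax(stats::rlnorm(n, log(med), log(gsd)), lo), hi)
  }
  draws <- data.frame(rr = stats::runif(n, 700, 1000),
                      lf = rln(11, 2.4, 2, 60),
                      hf = rln(3.5, 2.4, 1, 25),
                      noise = rln(2.2, 2.1, 0.5, 15),
                      ptt = stats::runif(n, 200, 300),
                      jit = stats::runif(n, ptt_jitter_range_ms[1],
                                         ptt_jitter_range_ms[2]))
  lapply(seq_len(n), function(i) {
    bp <- states[[(i - 1) %% 3 + 1]]
    cfg <- simulation_config(
      duration_s = duration_s,
      rr_mean_ms = draws$rr[i],
      rr_lf_amp_ms = draws$lf[i], rr_hf_amp_ms = draws$hf[i],
      rr_noise_sd_ms = draws$noise[i],
      ptt_mean_ms = draws$ptt[i], ptt_jitter_sd_ms = draws$jit[i],
      state_schedule = data.frame(start_s = 0, end_s = duration_s,
                                  sbp_mmhg = bp[1], dbp_mmhg = bp[2]),
      seed = (as.integer(seed) + i * 7919L) %% .Machine$integer.max)
    out <- render_record(cfg)
    if (artifact_rate > 0) {
      out$record <- inject_artifacts(out$record, artifact_rate,
                                     seed = cfg$seed)
    }
    out$config <- cfg
    out
  })
}

# beat times -> corrected, interpolated series; the outlier rule is applied
# to the raw NN series first and then once more to the 4 Hz interpolation
prepare_interval_series <- function(beat_times_s, source) {
  s <- build_interval_series(beat_times_s, source)
  s <- correct_outliers(s)
  s <- interpolate_series(s)
  fixed <- replace_outliers_vec(s$interp_values_ms)
  s$interp_values_ms <- fixed$values
  s
}

#' Run the end-to-end HRV/PRV comparison study
#'
#' For every record: ABP quality gate, segmentation into overlapping 5-min
#' windows, per-segment blood pressure state labelling, R-peak and pulse
#' onset detection, interval-series construction with outlier replacement
#' and 4 Hz interpolation, the 33-index set for both sources, and the
#' pooled per-state statistics layer (index summaries, Friedman source
#' comparison, Kruskal-Wallis state comparison with Bonferroni post hocs,
#' Bland-Altman/BAR agreement).
#'
#' @param records list of `waveform_record`s or of `list(record =, ...)`
#'   entries as produced by [simulate_cohort()].
#' @param segment_length_s,segment_overlap_s segmentation window (defaults
#'   300 and 10 s).
#' @param min_rgq ABP quality acceptance threshold in percent (default 80).
#' @param alpha significance level (default 0.05).
#' @param seed seed for the clustering step of the quality gate.
#' @param out_dir optional directory: tables are written as CSV and the
#'   full bundle as JSON.
#' @return a `study_report`: `segments` (per-segment index rows),
#'   `summary_by_state`, `friedman`, `kruskal`, `agreement`, `provenance`.
#' @export
run_study <- function(records, segment_length_s = 300, segment_overlap_s = 10,
                      min_rgq = 80, alpha = 0.05, seed = 1L, out_dir = NULL) {
  recs <- lapply(records, function(r) if (inherits(r, "waveform_record")) r else r$record)
  exclusions <- data.frame(record = integer(0), reason = character(0))
  rows <- list()
  n_accepted <- 0L
  for (i in seq_along(recs)) {
    qr <- filter_record(recs[[i]], seed = seed, min_rgq = min_rgq)
    if (!qr$accepted) {
      exclusions <- rbind(exclusions, data.frame(record = i, reason = qr$reason))
      next
    }
    n_accepted <- n_accepted + 1L
    segs <- segment_signals(recs[[i]], segment_length_s, segment_overlap_s)
    for (sg in segs) {
      row <- tryCatch(analyze_segment(sg, record_id = i), error = function(e) NULL)
      if (is.null(row)) {
        exclusions <- rbind(exclusions,
                            data.frame(record = i, reason = "segment analysis failed"))
      } else {
        rows <- c(rows, list(row))
      }
    }
  }
  if (!length(rows)) stop("empty cohort: no analyzable segments", call. = FALSE)
  segments <- do.call(rbind, rows)
  report <- structure(
    list(segments = segments,
         summary_by_state = summarize_by_state(segments),
         friedman = friedman_table(segments),
         kruskal = kruskal_table(segments, alpha = alpha),
         agreement = agreement_table(segments),
         provenance = list(records_in = length(recs),
                           records_accepted = n_accepted,
                           records_rejected = length(recs) - n_accepted,
                           exclusions = exclusions,
                           segment_count = nrow(segments) / 2,
                           seed = seed, alpha = alpha,
                           segment_length_s = segment_length_s,
                           segment_overlap_s = segment_overlap_s)),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# one segment -> two index rows (HRV from ECG, PRV from PPG) + state label
analyze_segment <- function(seg, record_id) {
  abp_f <- lowpass_abp(seg$abp, seg$fs)
  trend <- label_samples(extract_sbp_dbp_trends(abp_f, seg$fs))
  state <- label_segment(trend$state)
  hrv <- prepare_interval_series(detect_r_peaks(seg$ecg, seg$fs), "ECG")
  prv <- prepare_interval_series(detect_ppg_onsets(seg$ppg, seg$fs), "PPG")
  rbind(
    data.frame(record = record_id, offset_s = seg$offset_s %||% 0,
               state = state, source = "HRV", t(unlist(compute_all(hrv)))),
    data.frame(record = record_id, offset_s = seg$offset_s %||% 0,
               state = state, source = "PRV", t(unlist(compute_all(prv)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

segment_pairs <- function(segments) {
  key <- interaction(segments$record, segments$offset_s, drop = TRUE)
  hrv <- segments[segments$source == "HRV", ]
  prv <- segments[segments$source == "PRV", ]
  ord_h <- order(hrv$record, hrv$offset_s)
  ord_p <- order(prv$record, prv$offset_s)
  list(hrv = hrv[ord_h, ], prv = prv[ord_p, ])
}

summarize_by_state <- function(segments) {
  out <- list()
  for (st in unique(segments$state)) {
    for (src in c("HRV", "PRV")) {
      sub <- segments[segments$state == st & segments$source == src,
                      index_names, drop = FALSE]
      out[[length(out) + 1]] <-
        data.frame(state = st, source = src, index = index_names,
                   mean = vapply(sub, function(v) mean(v, na.rm = TRUE), numeric(1)),
                   sd = vapply(sub, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
                   n = vapply(sub, function(v) sum(!is.na(v)), numeric(1)))
    }
  }
  do.call(rbind, out)
}

friedman_table <- function(segments) {
  pr <- segment_pairs(segments)
  out <- list()
  for (st in unique(segments$state)) {
    sel <- pr$hrv$state == st
    if (sum(sel) < 6) next
    for (ix in index_names) {
      h <- pr$hrv[[ix]][sel]
      p <- pr$prv[[ix]][sel]
      ok <- !is.na(h) & !is.na(p)
      if (sum(ok) < 6) next
      ft <- compare_sources(h[ok], p[ok])
      out[[length(out) + 1]] <- data.frame(state = st, index = ix,
                                           p = ft$p, n = sum(ok))
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

kruskal_table <- function(segments, alpha = 0.05) {
  out <- list()
  for (src in c("HRV", "PRV")) {
    sub <- segments[segments$source == src, ]
    if (length(unique(sub$state)) < 2) next
    for (ix in index_names) {
      groups <- split(sub[[ix]], sub$state)
      groups <- lapply(groups, function(v) v[!is.na(v)])
      if (sum(lengths(groups) > 0) < 2) next
      sc <- compare_states(groups, alpha = alpha)
      out[[length(out) + 1]] <- data.frame(source = src, index = ix,
                                           kw_p = sc$kw_p,
                                           t(sc$pairwise_p))
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

agreement_table <- function(segments) {
  pr <- segment_pairs(segments)
  out <- list()
  for (st in unique(segments$state)) {
    sel <- pr$hrv$state == st
    if (sum(sel) < 2) next
    for (ix in index_names) {
      h <- pr$hrv[[ix]][sel]
      p <- pr$prv[[ix]][sel]
      ok <- !is.na(h) & !is.na(p)
      if (sum(ok) < 2) next
      ba <- bland_altman(h[ok], p[ok], index_name = ix, bp_state = st)
      out[[length(out) + 1]] <-
        data.frame(state = st, index = ix, bias = ba$bias,
                   loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                   bar = ba$bar, category = ba$category, n = sum(ok))
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.study_report <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("study_report: %d/%d records accepted, %d segments\n",
              pv$records_accepted, pv$records_in, pv$segment_count))
  if (!is.null(x$agreement)) {
    cat("agreement categories:\n")
    print(table(x$agreement$index == "AVNN", x$agreement$category))
  }
  invisible(x)
}

#' Write the study report bundle to disk
#'
#' CSV tables (`segments.csv`, `summary_by_state.csv`, `friedman.csv`,
#' `kruskal.csv`, `agreement.csv`) plus `results.json` with the full bundle
#' and `provenance.json`.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if absent).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("segments", "summary_by_state", "friedman", "kruskal", "agreement")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(lapply(unclass(report), function(x)
    if (is.data.frame(x)) x else x),
    file.path(out_dir, "results.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "rows", na = "null")
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows",
                       na = "null")
  invisible(out_dir)
}
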