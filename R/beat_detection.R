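#' Detect R peaks on an ECG channel
#'
#' Derivative - squaring - moving-window-integration detector with an
#' adaptive threshold and a 250 ms refractory period; each detection is
#' refined to the local ECG maximum so that on clean signal the returned
#' time is the R-peak sample itself.
#'
#' @param ecg numeric ECG waveform.
#' @param fs sampling rate (Hz).
#' @return numeric vector of R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 10 * fs) stop("need at least 10 s of ECG", call. = FALSE)
  if (max(ecg) - min(ecg) <= .Machine$double.eps) {
    stop("no peaks detected", call. = FALSE)
  }
  d <- c(0, diff(ecg))
  sq <- d^2
  w <- max(3L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  thr <- 0.2 * stats::quantile(mwi, 0.99, names = FALSE)
  if (thr <= 0) stop("no peaks detected", call. = FALSE)
  above <- mwi > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  refract <- round(0.25 * fs)
  half <- round(0.1 * fs)
  peaks <- integer(0)
  for (r in which(runs$values)) {
    center <- starts[r] + which.max(mwi[starts[r]:ends[r]]) - 1L
    lo <- max(1L, center - half)
    hi <- min(length(ecg), center + half)
    p <- lo + which.max(ecg[lo:hi]) - 1L
    if (!length(peaks) || p - peaks[length(peaks)] >= refract) {
      peaks <- c(peaks, p)
    }
  }
  if (!length(peaks)) stop("no peaks detected", call. = FALSE)
  (peaks - 1) / fs
}

#' Detect pulse onsets on a PPG channel by tangent intersection
#'
#' For each pulse the onset is the abscissa of the intersection between the
#' tangent line at the maximum-slope point of the rising edge and the
#' horizontal tangent through the preceding valley. The intersection is
#' clamped to the interval `[valley time, max-slope time]`; a flat rising
#' edge (non-finite or zero slope) falls back to the valley time and is
#' flagged.
#'
#' @param ppg numeric PPG waveform.
#' @param fs sampling rate (Hz).
#' @return numeric vector of onset times (s); attribute `"flagged"` marks
#'   onsets that fell back to the valley.
#' @export
detect_ppg_onsets <- function(ppg, fs) {
  if (length(ppg) < 2 * fs) stop("need at least 2 s of PPG", call. = FALSE)
  if (max(ppg) - min(ppg) <= .Machine$double.eps) {
    stop("no pulses detected", call. = FALSE)
  }
  peaks <- find_pulse_peaks(ppg, fs)
  if (length(peaks) < 2) stop("no pulses detected", call. = FALSE)
  onsets <- numeric(0)
  flagged <- logical(0)
  prev <- 1L
  for (p in peaks) {
    v <- prev + which.min(ppg[prev:p]) - 1L
    if (v < p) {
      d <- diff(ppg[v:p])
      m <- v + which.max(d) - 1L           # max forward-difference sample
      slope <- (ppg[m + 1L] - ppg[m]) * fs # per second
      t_m <- (m - 1) / fs
      t_v <- (v - 1) / fs
      if (is.finite(slope) && slope > 0) {
        t_on <- t_m - (ppg[m] - ppg[v]) / slope
        onsets <- c(onsets, min(max(t_on, t_v), t_m))
        flagged <- c(flagged, FALSE)
      } else {
        onsets <- c(onsets, t_v)
        flagged <- c(flagged, TRUE)
      }
    }
    prev <- p
  }
  keep <- !duplicated(onsets)
  structure(onsets[keep], flagged = flagged[keep])
}

# pulse peaks: local maxima of the smoothed PPG, 0.27 s minimum spacing,
# adaptive prominence floor
find_pulse_peaks <- function(ppg, fs) {
  w <- max(3L, round(0.05 * fs))
  sm <- as.numeric(stats::filter(ppg, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- ppg[is.na(sm)]
  d <- diff(sm)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  floor_amp <- min(sm, na.rm = TRUE) +
    0.4 * (stats::quantile(sm, 0.98, names = FALSE) - min(sm, na.rm = TRUE))
  cand <- cand[sm[cand] >= floor_amp]
  min_gap <- round(0.27 * fs)
  peaks <- integer(0)
  for (p in cand) {
    if (!length(peaks) || p - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, p)
    } else if (sm[p] > sm[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  peaks
}

#' Build a beat-to-beat interval series
#'
#' Normal-to-normal (NN) intervals in milliseconds between consecutive beat
#' times from one source (ECG R peaks or PPG pulse onsets).
#'
#' @param beat_times_s strictly increasing beat times in seconds.
#' @param source `"ECG"` or `"PPG"`.
#' @return an `interval_series`: `source`, `beat_times_s`, `nn_ms`,
#'   `corrected_mask`, and (after [interpolate_series()]) `interp_fs`,
#'   `interp_t_s`, `interp_values_ms`.
#' @export
build_interval_series <- function(beat_times_s, source = c("ECG", "PPG")) {
  source <- match.arg(source)
  if (length(beat_times_s) < 3) stop("need at least 3 beats", call. = FALSE)
  if (any(diff(beat_times_s) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  nn <- 1000 * diff(beat_times_s)
  structure(list(source = source, beat_times_s = beat_times_s, nn_ms = nn,
                 corrected_mask = rep(FALSE, length(nn)),
                 interp_fs = NA_real_, interp_t_s = numeric(0),
                 interp_values_ms = numeric(0)),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("interval_series (%s): %d NN intervals, mean %.1f ms, %d corrected%s\n",
              x$source, length(x$nn_ms), mean(x$nn_ms), sum(x$corrected_mask),
              if (length(x$interp_values_ms))
                sprintf(", interpolated at %g Hz (%d samples)",
                        x$interp_fs, length(x$interp_values_ms)) else ""))
  invisible(x)
}

# one pass of the 1.96 SD replacement rule on a bare numeric vector;
# returns the corrected values and the replacement mask
replace_outliers_vec <- function(v) {
  m <- mean(v)
  s <- stats::sd(v)
  # an (effectively) constant series has no outliers; guard against float
  # noise in accumulated beat times masquerading as dispersion
  if (!is.finite(s) || s <= 1e-9 * max(1, abs(m))) {
    return(list(values = v, mask = rep(FALSE, length(v))))
  }
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  out <- v < lo | v > hi
  corrected <- v
  med <- stats::median(v)
  for (i in which(out)) {
    prev <- corrected[seq_len(i - 1)]
    prev <- utils::tail(prev, 5)
    corrected[i] <- if (length(prev)) mean(prev) else med
  }
  list(values = corrected, mask = out)
}

#' Replace outlying intervals
#'
#' Values outside the mean plus or minus 1.96 standard deviations of the
#' uncorrected series are replaced, left to right, by the mean of the five
#' previous (already corrected) values; with fewer than five predecessors
#' all available ones are used, and with none the series median. The same
#' rule is applied to the interpolated series when present.
#'
#' @param series an `interval_series`.
#' @return the series with `nn_ms` corrected and `corrected_mask` updated.
#' @export
correct_outliers <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  if (length(series$nn_ms) < 6) stop("need at least 6 intervals", call. = FALSE)
  fixed <- replace_outliers_vec(series$nn_ms)
  series$nn_ms <- fixed$values
  series$corrected_mask <- fixed$mask
  if (length(series$interp_values_ms)) {
    fixed_i <- replace_outliers_vec(series$interp_values_ms)
    series$interp_values_ms <- fixed_i$values
  }
  series
}

#' Resample an interval series on a uniform grid
#'
#' Natural cubic spline through the knots (each NN interval anchored at its
#' ending beat time) evaluated on a uniform grid at `fs_out` Hz spanning the
#' knot range; no extrapolation beyond the first/last knot.
#'
#' @param series an `interval_series` with at least 4 intervals.
#' @param fs_out output sampling rate (Hz, default 4).
#' @return the series with `interp_fs`, `interp_t_s` and
#'   `interp_values_ms` filled in.
#' @export
interpolate_series <- function(series, fs_out = 4) {
  stopifnot(inherits(series, "interval_series"))
  if (length(series$nn_ms) < 4) stop("need at least 4 intervals", call. = FALSE)
  x <- series$beat_times_s[-1]
  y <- series$nn_ms
  # grid anchored at the first knot (not absolute time) so a pure time shift
  # of the beats shifts the interpolated series without changing its values
  grid <- x[1] + seq(0, x[length(x)] - x[1], by = 1 / fs_out)
  f <- stats::splinefun(x, y, method = "natural")
  series$interp_fs <- fs_out
  series$interp_t_s <- grid
  series$interp_values_ms <- f(grid)
  series
}

#' Serialize an interval series to CSV
#'
#' Beat-level rows (`beat_time_s`, `nn_ms`, `corrected`); when an
#' interpolated series exists it is written alongside as
#' `<path>_interp.csv` (`t_s`, `nn_ms`).
#'
#' @param series an `interval_series`.
#' @param path output CSV path.
#' @export
write_interval_series <- function(series, path) {
  utils::write.csv(data.frame(beat_time_s = series$beat_times_s[-1],
                              nn_ms = series$nn_ms,
                              corrected = series$corrected_mask),
                   path, row.names = FALSE)
  if (length(series$interp_values_ms)) {
    utils::write.csv(data.frame(t_s = series$interp_t_s,
                                nn_ms = series$interp_values_ms),
                     sub("\\.csv$", "_interp.csv", path), row.names = FALSE)
  }
  invisible(path)
}
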