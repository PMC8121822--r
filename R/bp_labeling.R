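#' Zero-phase lowpass filtering of the ABP waveform
#'
#' Applies a fourth-order Butterworth lowpass with 12 Hz cutoff in
#' forward-backward (zero-phase) fashion, the conventional pre-processing
#' before extracting systolic/diastolic trends from invasive arterial
#' pressure.
#'
#' @param abp numeric ABP waveform (mmHg).
#' @param fs sampling rate in Hz; must exceed twice the 12 Hz cutoff.
#' @param cutoff_hz cutoff frequency (default 12).
#' @param order filter order (default 4).
#' @return filtered waveform, same length as the input.
#' @export
lowpass_abp <- function(abp, fs, cutoff_hz = 12, order = 4) {
  if (fs <= 2 * cutoff_hz) {
    stop("sampling rate must exceed twice the cutoff frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # mirror-pad both ends so the forward-backward pass has no edge transient
  np <- min(length(abp) - 1, round(fs))
  pad <- c(2 * abp[1] - abp[(np + 1):2],
           abp,
           2 * abp[length(abp)] - abp[(length(abp) - 1):(length(abp) - np)])
  out <- as.numeric(signal::filtfilt(bf, pad))
  out[(np + 1):(np + length(abp))]
}

#' Systolic and diastolic blood pressure trends from ABP
#'
#' Detects cardiac cycles on the (filtered) ABP, takes per-cycle maxima as
#' systolic knots and per-cycle minima as diastolic knots, removes
#' implausible knots (outside 20-300 mmHg, or deviating more than 30 mmHg
#' from the median of the five neighbouring knots), and interpolates each
#' knot set with a cubic spline onto the full sample grid.
#'
#' @param abp filtered ABP waveform.
#' @param fs sampling rate (Hz).
#' @return a `bp_trend` object: `t`, `sbp`, `dbp` per sample (state not yet
#'   assigned; see [label_samples()]).
#' @export
extract_sbp_dbp_trends <- function(abp, fs) {
  onsets <- detect_abp_onsets(abp, fs)
  n_cyc <- length(onsets) - 1
  if (n_cyc < 2) stop("need at least 2 cycles for trend extraction", call. = FALSE)
  sbp_idx <- dbp_idx <- integer(n_cyc)
  sbp_val <- dbp_val <- numeric(n_cyc)
  for (k in seq_len(n_cyc)) {
    seg <- onsets[k]:(onsets[k + 1] - 1L)
    sbp_idx[k] <- seg[which.max(abp[seg])]
    dbp_idx[k] <- seg[which.min(abp[seg])]
    sbp_val[k] <- abp[sbp_idx[k]]
    dbp_val[k] <- abp[dbp_idx[k]]
  }
  keep_s <- valid_knots(sbp_val)
  keep_d <- valid_knots(dbp_val)
  if (sum(keep_s) < 2 || sum(keep_d) < 2) {
    stop("fewer than 2 valid pressure knots", call. = FALSE)
  }
  t <- (seq_along(abp) - 1) / fs
  sbp <- spline_trend(t[sbp_idx[keep_s]], sbp_val[keep_s], t)
  dbp <- spline_trend(t[dbp_idx[keep_d]], dbp_val[keep_d], t)
  sbp <- pmax(sbp, dbp)  # guard against spline crossings at the edges
  structure(list(t = t, sbp = sbp, dbp = dbp, state = NULL),
            class = "bp_trend")
}

# knot correction: physiological range plus neighbourhood-median rule
valid_knots <- function(v) {
  keep <- v >= 20 & v <= 300
  for (k in seq_along(v)) {
    nb <- setdiff(max(1, k - 2):min(length(v), k + 2), k)
    if (length(nb) && abs(v[k] - stats::median(v[nb])) > 30) keep[k] <- FALSE
  }
  keep
}

# natural cubic spline through the knots, held constant beyond the ends
spline_trend <- function(x, y, xout) {
  f <- stats::splinefun(x, y, method = "natural")
  out <- f(xout)
  out[xout < x[1]] <- y[1]
  out[xout > x[length(x)]] <- y[length(y)]
  out
}

# vectorized BP state rule shared by the labeller and the synthetic truth
label_bp_state <- function(sbp, dbp) {
  hypo <- sbp < 90 | dbp < 60
  hyper <- sbp > 140 | dbp > 90
  state <- rep("normotension", length(sbp))
  state[hyper] <- "hypertension"
  state[hypo] <- "hypotension"  # hypotension wins if both rules fire
  factor(state, levels = c("hypotension", "normotension", "hypertension"))
}

#' Classify each sample of a BP trend into a blood pressure state
#'
#' Hypertension when SBP > 140 mmHg or DBP > 90 mmHg; hypotension when
#' SBP < 90 mmHg or DBP < 60 mmHg; normotension otherwise. If both rules
#' fire on the same sample (e.g. SBP 150 with DBP 55) the sample is labelled
#' hypotension, the more safety-critical state in ICU monitoring.
#'
#' @param trend a `bp_trend` from [extract_sbp_dbp_trends()].
#' @return the trend with the per-sample `state` factor filled in.
#' @export
label_samples <- function(trend) {
  stopifnot(inherits(trend, "bp_trend"))
  trend$state <- label_bp_state(trend$sbp, trend$dbp)
  trend
}

#' Majority blood pressure label of a segment
#'
#' Returns the most frequent per-sample state in the segment. Ties are
#' broken toward the non-normotensive candidate; a hypotension/hypertension
#' tie is broken toward hypotension.
#'
#' @param states factor/character vector of per-sample states for one
#'   segment.
#' @return single character label.
#' @export
label_segment <- function(states) {
  states <- as.character(states)
  stopifnot(length(states) > 0)
  counts <- table(factor(states,
                         levels = c("hypotension", "hypertension", "normotension")))
  # table order doubles as tie-break priority: hypo > hyper > normo
  names(counts)[which.max(counts)]
}

#' @export
print.bp_trend <- function(x, ...) {
  cat(sprintf("bp_trend: %d samples, SBP %.0f-%.0f mmHg, DBP %.0f-%.0f mmHg\n",
              length(x$t), min(x$sbp), max(x$sbp), min(x$dbp), max(x$dbp)))
  if (!is.null(x$state)) print(table(x$state))
  invisible(x)
}

#' Plot a BP trend with its state labels
#'
#' @param x a labelled `bp_trend`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bp_trend <- function(x, ...) {
  graphics::plot(x$t, x$sbp, type = "l", xlab = "time (s)",
                 ylab = "pressure (mmHg)",
                 ylim = range(c(x$sbp, x$dbp)), ...)
  graphics::lines(x$t, x$dbp, lty = 3)
  graphics::abline(h = c(90, 140), col = "grey70", lty = 2)
  if (!is.null(x$state)) {
    code <- c(hypotension = 1, normotension = 2, hypertension = 3)[as.character(x$state)]
    graphics::lines(x$t, min(x$dbp) + 5 * code, lty = 2, col = "grey40")
  }
  invisible(x)
}
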