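#' Simulation configuration for coupled ECG/PPG/ABP records
#'
#' Bundles every parameter of the synthetic record generator: the RR-interval
#' process (mean level plus LF and HF sinusoidal modulation plus white
#' jitter), the beat-to-beat pulse transit time (PTT) between the ECG R peak
#' and the PPG pulse onset, the scheduled systolic/diastolic blood pressure
#' targets, and the ABP artifact rate.
#'
#' @param duration_s record duration in seconds. Records meant for 5-min
#'   segmentation need `duration_s >= 300`.
#' @param fs sampling rate in Hz for all three channels (default 125).
#' @param rr_mean_ms mean RR interval in milliseconds.
#' @param rr_lf_amp_ms,rr_lf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   low-frequency RR oscillation (baroreflex band, ~0.1 Hz).
#' @param rr_hf_amp_ms,rr_hf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   high-frequency RR oscillation (respiratory band, ~0.25 Hz).
#' @param rr_noise_sd_ms standard deviation (ms) of the white beat-to-beat
#'   RR jitter.
#' @param ptt_mean_ms mean pulse transit time in milliseconds (>= 0).
#' @param ptt_jitter_sd_ms standard deviation (ms) of the i.i.d. Gaussian
#'   beat-to-beat PTT jitter. Zero makes PPG a pure time shift of the ECG
#'   beat sequence, so pulse-derived and R-peak-derived interval series
#'   coincide exactly before sampling quantization.
#' @param state_schedule data.frame with columns `start_s`, `end_s`,
#'   `sbp_mmhg`, `dbp_mmhg`: non-overlapping intervals covering
#'   `[0, duration_s)` giving the target per-cycle ABP maxima/minima.
#' @param artifact_rate expected ABP artifacts per minute (Poisson).
#' @param seed integer RNG seed; every stochastic element of the record is a
#'   deterministic function of the config including this seed.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(duration_s = 330,
                              fs = 125,
                              rr_mean_ms = 800,
                              rr_lf_amp_ms = 15, rr_lf_freq_hz = 0.095,
                              rr_hf_amp_ms = 8, rr_hf_freq_hz = 0.25,
                              rr_noise_sd_ms = 5,
                              ptt_mean_ms = 250,
                              ptt_jitter_sd_ms = 0,
                              state_schedule = NULL,
                              artifact_rate = 0,
                              seed = 1L) {
  if (is.null(state_schedule)) {
    state_schedule <- data.frame(start_s = 0, end_s = duration_s,
                                 sbp_mmhg = 120, dbp_mmhg = 80)
  }
  cfg <- list(duration_s = duration_s, fs = fs,
              rr_mean_ms = rr_mean_ms,
              rr_lf_amp_ms = rr_lf_amp_ms, rr_lf_freq_hz = rr_lf_freq_hz,
              rr_hf_amp_ms = rr_hf_amp_ms, rr_hf_freq_hz = rr_hf_freq_hz,
              rr_noise_sd_ms = rr_noise_sd_ms,
              ptt_mean_ms = ptt_mean_ms,
              ptt_jitter_sd_ms = ptt_jitter_sd_ms,
              state_schedule = state_schedule,
              artifact_rate = artifact_rate,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$fs > 0, cfg$ptt_mean_ms >= 0,
            cfg$ptt_jitter_sd_ms >= 0, cfg$rr_noise_sd_ms >= 0,
            cfg$artifact_rate >= 0)
  if (cfg$rr_mean_ms <= 0) {
    stop("rr_mean_ms must be positive", call. = FALSE)
  }
  sch <- cfg$state_schedule
  req <- c("start_s", "end_s", "sbp_mmhg", "dbp_mmhg")
  if (!all(req %in% names(sch))) {
    stop("state_schedule needs columns start_s, end_s, sbp_mmhg, dbp_mmhg",
         call. = FALSE)
  }
  sch <- sch[order(sch$start_s), ]
  if (sch$start_s[1] > 0 || sch$end_s[nrow(sch)] < cfg$duration_s ||
      (nrow(sch) > 1 && any(abs(sch$start_s[-1] - sch$end_s[-nrow(sch)]) > 1e-9))) {
    stop("state_schedule must cover [0, duration_s) without gaps or overlap",
         call. = FALSE)
  }
  if (any(sch$sbp_mmhg <= sch$dbp_mmhg)) {
    stop("scheduled SBP must exceed DBP", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Field names match the arguments of [simulation_config()]; the
#' `state_schedule` entry is a list of `{start_s, end_s, sbp_mmhg, dbp_mmhg}`
#' records.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$state_schedule) && !is.data.frame(raw$state_schedule)) {
    raw$state_schedule <- do.call(rbind, lapply(raw$state_schedule, as.data.frame))
  }
  do.call(simulation_config, raw)
}

# Independent RNG substreams so toggling artifacts never perturbs the RR
# series: each consumer reseeds from a fixed offset of the record seed.
substream_seed <- function(seed, which) {
  offsets <- c(rr = 101L, ptt = 211L, artifact = 307L, cluster = 401L)
  (as.integer(seed) + offsets[[which]]) %% .Machine$integer.max
}

#' Generate the beat-to-beat RR process
#'
#' RR intervals follow a mean level plus LF and HF sinusoids evaluated at the
#' (cumulative) beat times, plus seeded Gaussian jitter; any non-positive
#' draw is resampled. Beat times start at 0 and accumulate until the record
#' duration is reached.
#'
#' @param config a [simulation_config()].
#' @return list with `beat_times_s` (first beat at 0) and `rr_ms`
#'   (`length(beat_times_s) - 1` intervals).
#' @export
generate_rr_process <- function(config) {
  validate_simulation_config(config)
  rng <- local_rng(substream_seed(config$seed, "rr"))
  on.exit(rng())
  t <- 0
  beats <- numeric(0)
  rr <- numeric(0)
  while (t <= config$duration_s + 1e-9) {
    beats <- c(beats, t)
    rr_i <- config$rr_mean_ms +
      config$rr_lf_amp_ms * sin(2 * pi * config$rr_lf_freq_hz * t) +
      config$rr_hf_amp_ms * sin(2 * pi * config$rr_hf_freq_hz * t)
    if (config$rr_noise_sd_ms > 0) {
      eps <- stats::rnorm(1, 0, config$rr_noise_sd_ms)
      while (rr_i + eps <= 0) eps <- stats::rnorm(1, 0, config$rr_noise_sd_ms)
      rr_i <- rr_i + eps
    }
    if (rr_i <= 0) stop("deterministic RR component non-positive", call. = FALSE)
    rr <- c(rr, rr_i)
    t <- t + rr_i / 1000
  }
  # drop the interval that crosses the record end
  list(beat_times_s = beats, rr_ms = rr[-length(rr)])
}

# save/restore the global RNG state around seeded internals
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# analytic channel templates ------------------------------------------------

# Narrow positive Gaussian spike standing in for the QRS complex.
ecg_template <- function(dt_s) exp(-0.5 * (dt_s / 0.012)^2)

# Pulse wave: linear systolic upstroke (120 ms) into an exponential
# diastolic decay. The linear rise makes the tangent at the maximum-slope
# point pass exactly through the pulse foot, so the tangent-intersection
# fiducial recovers the true onset; the strictly decaying tail gives every
# cycle a single unambiguous valley. dt_s <= 0 contributes nothing.
pulse_rise_s <- 0.12
pulse_template <- function(dt_s) {
  y <- numeric(length(dt_s))
  rise <- dt_s > 0 & dt_s <= pulse_rise_s
  decay <- dt_s > pulse_rise_s
  y[rise] <- dt_s[rise] / pulse_rise_s
  y[decay] <- exp(-(dt_s[decay] - pulse_rise_s) / 0.25)
  y
}

# ABP beat shape: smooth gamma-like rise and decay (no corners), so the
# per-cycle maximum survives 12 Hz lowpass filtering essentially unchanged;
# strictly increasing to a single peak, then strictly decreasing
abp_template <- function(dt_s) {
  y <- numeric(length(dt_s))
  pos <- dt_s > 0
  u <- dt_s[pos] / 0.09
  # the 1.2 exponent keeps the diastolic tail strictly decreasing without
  # underflowing to a constant within one cycle
  y[pos] <- u^2 * exp(-u^1.2)
  y
}

# per-sample SBP/DBP target series: schedule steps with 5 s linear ramps
schedule_trends <- function(config) {
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  sch <- config$state_schedule[order(config$state_schedule$start_s), ]
  sbp <- numeric(n)
  dbp <- numeric(n)
  for (k in seq_len(nrow(sch))) {
    idx <- t >= sch$start_s[k] & t < sch$end_s[k]
    sbp[idx] <- sch$sbp_mmhg[k]
    dbp[idx] <- sch$dbp_mmhg[k]
  }
  sbp[t >= sch$end_s[nrow(sch)]] <- sch$sbp_mmhg[nrow(sch)]
  dbp[t >= sch$end_s[nrow(sch)]] <- sch$dbp_mmhg[nrow(sch)]
  ramp <- 5
  if (nrow(sch) > 1) {
    for (k in 2:nrow(sch)) {
      t0 <- sch$start_s[k]
      idx <- which(t >= t0 & t < t0 + ramp)
      if (length(idx)) {
        w <- (t[idx] - t0) / ramp
        sbp[idx] <- (1 - w) * sch$sbp_mmhg[k - 1] + w * sch$sbp_mmhg[k]
        dbp[idx] <- (1 - w) * sch$dbp_mmhg[k - 1] + w * sch$dbp_mmhg[k]
      }
    }
  }
  list(t = t, sbp = sbp, dbp = dbp)
}

#' Render a synthetic three-channel waveform record
#'
#' Places a Gaussian QRS spike at every beat time (ECG), a pulse template
#' with its onset one pulse transit time later (PPG), and builds ABP cycle by
#' cycle so that each cycle's maximum and minimum track the scheduled
#' systolic/diastolic targets (5 s linear ramps across schedule boundaries).
#' All channels are sampled on the common 1/fs grid; the returned ground
#' truth keeps the continuous-time (pre-quantization) beat times.
#'
#' @param config a [simulation_config()].
#' @return list with components `record` (a `waveform_record`: `t_s`, `ecg`,
#'   `ppg`, `abp`, `fs`) and `truth` (a `ground_truth`: true R times, true
#'   pulse onset times, PTT series, per-sample SBP/DBP trends and BP state).
#' @export
render_record <- function(config) {
  validate_simulation_config(config)
  rrp <- generate_rr_process(config)
  beats <- rrp$beat_times_s
  nb <- length(beats)
  rng <- local_rng(substream_seed(config$seed, "ptt"))
  on.exit(rng())
  ptt_ms <- config$ptt_mean_ms + if (config$ptt_jitter_sd_ms > 0) {
    stats::rnorm(nb, 0, config$ptt_jitter_sd_ms)
  } else rep(0, nb)
  ptt_ms <- pmax(ptt_ms, 0)
  ppg_beats <- beats + ptt_ms / 1000

  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  ecg <- numeric(n)
  ppg <- numeric(n)
  for (b in beats) {
    idx <- which(t >= b - 0.06 & t <= b + 0.06)
    ecg[idx] <- ecg[idx] + ecg_template(t[idx] - b)
  }
  for (b in ppg_beats) {
    idx <- which(t >= b & t <= b + 2.0)
    ppg[idx] <- ppg[idx] + pulse_template(t[idx] - b)
  }

  tr <- schedule_trends(config)
  abp <- numeric(n)
  # cycle k spans [beat_k, beat_{k+1}); last cycle runs to record end
  bounds <- c(beats, config$duration_s)
  for (k in seq_len(nb)) {
    idx <- which(t >= bounds[k] & t < bounds[k + 1])
    if (!length(idx)) next
    shape <- abp_template(t[idx] - bounds[k])
    rng_sh <- range(shape)
    unit <- if (diff(rng_sh) > 0) (shape - rng_sh[1]) / diff(rng_sh) else shape * 0
    i0 <- idx[1]
    abp[idx] <- tr$dbp[i0] + unit * (tr$sbp[i0] - tr$dbp[i0])
  }
  # lead-in before the first beat: hold the first diastolic level
  pre <- t < bounds[1]
  abp[pre] <- tr$dbp[which(!pre)[1]]

  record <- structure(list(t_s = t, ecg = ecg, ppg = ppg, abp = abp,
                           fs = config$fs, source = "synthetic",
                           artifact_log = empty_artifact_log()),
                      class = "waveform_record")
  truth <- structure(list(ecg_beat_times_s = beats,
                          ppg_beat_times_s = ppg_beats,
                          ptt_series_ms = ptt_ms,
                          sbp_trend = tr$sbp, dbp_trend = tr$dbp,
                          state_per_sample = label_bp_state(tr$sbp, tr$dbp)),
                     class = "ground_truth")
  list(record = record, truth = truth)
}

empty_artifact_log <- function() {
  data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0))
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("waveform_record: %.1f s at %g Hz (%d samples), %d artifact(s)\n",
              length(x$t_s) / x$fs, x$fs, length(x$t_s), nrow(x$artifact_log)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d beats, PTT %.0f ms (SD %.1f ms)\n",
              length(x$ecg_beat_times_s), mean(x$ptt_series_ms),
              stats::sd(x$ptt_series_ms)))
  invisible(x)
}

#' Inject artifacts into the ABP channel
#'
#' Corrupts the ABP channel with flat-lines (0.5-3 s of held value),
#' saturation clips and spike transients at Poisson-distributed positions,
#' and records every corruption in the returned artifact log so tests can
#' identify the affected cardiac cycles. ECG and PPG are untouched.
#'
#' @param record a `waveform_record`.
#' @param rate expected artifacts per minute (Poisson, seeded); ignored when
#'   `at` is given.
#' @param kinds subset of `c("flatline", "saturation", "spike")`.
#' @param seed RNG seed for artifact placement.
#' @param at optional data.frame (`kind`, `start_s`, `len_s`) placing
#'   artifacts deterministically instead of drawing them.
#' @return the record with corrupted `abp` and an appended `artifact_log`
#'   (`kind`, `start_s`, `end_s`).
#' @export
inject_artifacts <- function(record, rate,
                             kinds = c("flatline", "saturation", "spike"),
                             seed = 1L, at = NULL) {
  stopifnot(inherits(record, "waveform_record"), rate >= 0)
  bad <- setdiff(if (is.null(at)) kinds else at$kind,
                 c("flatline", "saturation", "spike"))
  if (length(bad)) stop("unknown artifact kind: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(at)) {
    if (rate == 0) return(record)
    rng <- local_rng(substream_seed(seed, "artifact"))
    on.exit(rng())
    dur_min <- length(record$t_s) / record$fs / 60
    n_events <- stats::rpois(1, rate * dur_min)
    if (n_events == 0) return(record)
    at <- data.frame(
      kind = sample(kinds, n_events, replace = TRUE),
      start_s = stats::runif(n_events, 0, max(record$t_s) - 3))
    at$len_s <- ifelse(at$kind == "flatline", stats::runif(n_events, 0.5, 3),
                       ifelse(at$kind == "saturation",
                              stats::runif(n_events, 0.5, 2),
                              stats::runif(n_events, 0.08, 0.2)))
  }
  fs <- record$fs
  n <- length(record$abp)
  log <- vector("list", nrow(at))
  for (e in seq_len(nrow(at))) {
    kind <- at$kind[e]
    i0 <- max(1L, round(at$start_s[e] * fs) + 1L)
    i1 <- min(n, i0 + round(at$len_s[e] * fs))
    idx <- i0:i1
    record$abp[idx] <- switch(kind,
                              flatline = record$abp[i0],
                              saturation = 300,
                              spike = record$abp[idx] +
                                180 * exp(-0.5 * ((idx - mean(idx)) / (0.02 * fs))^2))
    log[[e]] <- data.frame(kind = kind, start_s = (i0 - 1) / fs,
                           end_s = (i1 - 1) / fs)
  }
  record$artifact_log <- rbind(record$artifact_log, do.call(rbind, log))
  record
}

#' Write / read a waveform record as plain CSV
#'
#' Columns `time_s, ecg, ppg, abp`; the sampling rate is recovered from the
#' time column on read. Ground truth can be stored alongside as JSON with
#' [write_ground_truth()].
#'
#' @param record a `waveform_record`.
#' @param path output CSV path.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(data.frame(time_s = record$t_s, ecg = record$ecg,
                              ppg = record$ppg, abp = record$abp),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(t_s = d$time_s, ecg = d$ecg, ppg = d$ppg, abp = d$abp,
                 fs = 1 / stats::median(diff(d$time_s)), source = path,
                 artifact_log = empty_artifact_log()),
            class = "waveform_record")
}

#' @rdname write_record_csv
#' @param truth a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
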