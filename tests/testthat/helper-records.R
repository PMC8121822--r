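# shared fixtures, built in code

# clean constant-schedule record; cached per parameter set so several test
# files can reuse the same rendering
clean_record <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3, duration_s = 330, rr_mean_ms = 800, rr_noise_sd_ms = 0,
           rr_lf_amp_ms = 0, rr_hf_amp_ms = 0, ptt_jitter_sd_ms = 0,
           sbp = 120, dbp = 80) {
    key <- paste(seed, duration_s, rr_mean_ms, rr_noise_sd_ms, rr_lf_amp_ms,
                 rr_hf_amp_ms, ptt_jitter_sd_ms, sbp, dbp, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- simulation_config(
        duration_s = duration_s, rr_mean_ms = rr_mean_ms,
        rr_noise_sd_ms = rr_noise_sd_ms, rr_lf_amp_ms = rr_lf_amp_ms,
        rr_hf_amp_ms = rr_hf_amp_ms, ptt_jitter_sd_ms = ptt_jitter_sd_ms,
        state_schedule = data.frame(start_s = 0, end_s = duration_s,
                                    sbp_mmhg = sbp, dbp_mmhg = dbp),
        seed = seed)
      cache[[key]] <- c(render_record(cfg), list(config = cfg))
    }
    cache[[key]]
  }
})

# fraction of detected ABP cycles overlapping any logged artifact
corrupted_cycle_fraction <- function(record) {
  onsets <- detect_abp_onsets(record$abp, record$fs)
  log <- record$artifact_log
  n_cyc <- length(onsets) - 1
  bad <- vapply(seq_len(n_cyc), function(k) {
    s0 <- (onsets[k] - 1) / record$fs
    s1 <- (onsets[k + 1] - 1) / record$fs
    any(log$start_s < s1 & log$end_s > s0)
  }, logical(1))
  mean(bad)
}
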