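# Full-pipeline cohort runs are expensive; cache them so several acceptance
# checks can share one run.
cohort_cache <- new.env(parent = emptyenv())

run_cohort_pipeline <- function(group, seed = 1, duration_s = 1200) {
  key <- paste(group, seed, duration_s, sep = "|")
  if (!is.null(cohort_cache[[key]])) return(cohort_cache[[key]])
  cfg <- make_fixture_config(group, seed = seed)
  mice <- lapply(seq_len(cfg$n_mice), function(mi) {
    sim <- simulate_recording(cfg, mi, duration_s = duration_s)
    fs <- cfg$fs
    x <- bandpass(sim$recording$vagus, fs)
    bursts <- detect_bursts(x, fs)
    thr <- adaptive_threshold(x, bursts, fs)
    spikes <- detect_spikes(x, thr, fs)
    units <- sort_recording(spikes, sim$recording$ecg, fs, seed = seed)
    keep <- units[!units$cardiac_flag & !units$unstable_flag, ]
    keep$mouse_id <- rep(mi, nrow(keep))
    keep$unit_id <- if (nrow(keep)) paste0("m", mi, "-c", keep$unit) else
      character(0)
    list(units = keep, bursts = bursts, duration = duration_s)
  })
  units <- dplyr::bind_rows(lapply(mice, `[[`, "units"))
  res <- list(cfg = cfg, mice = mice, units = units)
  cohort_cache[[key]] <- res
  res
}
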