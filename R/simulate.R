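#' Synthetic cuff-electrode recordings with ground truth
#'
#' `simulate_recording()` synthesizes one mouse's two-channel recording
#' (vagus cuff + ECG) from a [sim_config()]: per-unit CAP templates placed at
#' inhomogeneous-Poisson spike times, Gaussian noise whose SD rises inside
#' respiratory bursts, and cardiac deflections shared (within 1 ms) between
#' the two channels. The ECG channel carries cardiac deflections and noise
#' but no CAP energy.
#'
#' Respiratory bursts follow a renewal process: durations are normal
#' (truncated positive) and onset-to-onset periods normal truncated at
#' duration + 50 ms. Unit rates follow the piecewise-constant law described
#' in [sim_config()]; spike counts per constant-rate segment are Poisson and
#' times uniform within the segment, so identical `(config, seed)` give
#' bit-identical output.
#'
#' @param config A validated [sim_config()].
#' @param mouse_index Mouse number, `1..config$n_mice`.
#' @param duration_s Optional truncated session length (seconds); defaults
#'   to the mouse's full session plan. Useful for baseline-only or excerpt
#'   simulations.
#' @return A list with elements `recording` (class `cap_recording`: `vagus`,
#'   `ecg`, `fs`, `events`, `metadata`) and `truth` (class `cap_truth`:
#'   planted `spikes`, `units` with planted per-period rates, `bursts`,
#'   `cardiac` times, `plan`).
#' @examples
#' cfg <- make_fixture_config("paper-CON", seed = 1)
#' sim <- simulate_recording(cfg, mouse_index = 1, duration_s = 10)
#' sim$recording
#' head(sim$truth$spikes)
#' @export
simulate_recording <- function(config, mouse_index, duration_s = NULL) {
  validate_sim_config(config)
  stopifnot(mouse_index >= 1, mouse_index <= config$n_mice)
  plan <- config$plans[[mouse_index]]
  duration <- if (is.null(duration_s)) plan$total_s else duration_s
  stopifnot(duration > 0)
  fs <- config$fs
  n <- round(duration * fs)

  withr::with_seed(derive_seed(config$seed, mouse_index, salt = 1L), {
    bursts <- simulate_bursts(duration, config$resp_burst_duration,
                              config$resp_burst_period)
    cardiac <- simulate_cardiac_times(duration, config$cardiac_rate)
    units <- dplyr::filter(config$units, .data$mouse_id == mouse_index)
    spike_list <- lapply(seq_len(nrow(units)), function(i) {
      u <- units[i, ]
      simulate_unit_spikes(u$baseline_rate, u$burst_gain,
                           period_multipliers(u$response_c1, u$response_c2),
                           plan, bursts, duration, config$ramp_s)
    })

    noise <- rnorm(n, sd = config$noise_sd_base)
    mask <- intervals_to_mask(bursts, n, fs)
    noise[mask] <- noise[mask] * config$noise_burst_multiplier
    vagus <- noise
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      pre <- if ("pre_ratio" %in% names(u)) u$pre_ratio else 0
      tm <- make_cap_template(fs, u$width_factor, u$amplitude_uV,
                              u$amp_ratio, pre_ratio = pre)
      centers <- round(spike_list[[i]] * fs) + 1L
      vagus <- add_template_cpp(vagus, centers, tm$wave, tm$align)
    }
    card_tm <- make_cardiac_vagus_template(fs)
    card_centers <- round(cardiac * fs) + 1L
    vagus <- add_template_cpp(vagus, card_centers, card_tm$wave, card_tm$align)

    ecg <- rnorm(n, sd = config$ecg_noise_sd)
    ecg_tm <- make_ecg_template(fs)
    ecg_jitter <- round(runif(length(cardiac), -0.5e-3, 0.5e-3) * fs)
    ecg <- add_template_cpp(ecg, card_centers + as.integer(ecg_jitter),
                            ecg_tm$wave, ecg_tm$align)

    cyt <- period_cytokine(plan)
    events <- tibble::tibble(
      label = unname(cyt),
      time_s = plan$inj_s
    )
    events <- dplyr::filter(events, .data$time_s < duration)

    spikes <- tibble::tibble(
      unit_id = rep(units$unit_id, lengths(spike_list)),
      time_s = unlist(spike_list)
    )
    mults <- purrr::map2(units$response_c1, units$response_c2,
                         period_multipliers)
    truth_units <- dplyr::mutate(
      units,
      n_spikes = lengths(spike_list),
      f_BL = .data$overall_rate,
      f_C1 = .data$overall_rate * purrr::map_dbl(mults, "C1"),
      f_C2 = .data$overall_rate * purrr::map_dbl(mults, "C2")
    )

    recording <- structure(list(
      vagus = vagus, ecg = ecg, fs = fs, events = events,
      metadata = tibble::tibble(group = config$group_label,
                                mouse_id = mouse_index,
                                duration_s = duration)
    ), class = "cap_recording")
    truth <- structure(list(
      spikes = spikes, units = truth_units, bursts = bursts,
      cardiac = cardiac, plan = plan
    ), class = "cap_truth")
    list(recording = recording, truth = truth)
  })
}

#' @export
print.cap_recording <- function(x, ...) {
  cat(sprintf(
    "<cap_recording> %s mouse %d: %.1f s at %d Hz (%d samples), %d event(s)\n",
    x$metadata$group, x$metadata$mouse_id, x$metadata$duration_s, x$fs,
    length(x$vagus), nrow(x$events)))
  invisible(x)
}

# Renewal respiratory-burst process; half-open [start, end) intervals in s.
simulate_bursts <- function(duration, dur_ms, per_ms) {
  rtrunc_norm <- function(mean, sd, lower) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > lower) return(x)
    }
  }
  onset <- runif(1, 0, per_ms[1] / 1000)
  starts <- c(); ends <- c()
  while (onset < duration) {
    d <- rtrunc_norm(dur_ms[1], dur_ms[2], 10) / 1000
    starts <- c(starts, onset)
    ends <- c(ends, min(onset + d, duration))
    onset <- onset + rtrunc_norm(per_ms[1], per_ms[2], dur_ms[1] + 50) / 1000
  }
  tibble::tibble(start = starts, end = ends)
}

# Near-periodic heartbeat times with sub-ms jitter.
simulate_cardiac_times <- function(duration, rate) {
  if (rate <= 0) return(numeric(0))
  t <- seq(runif(1, 0, 1 / rate), duration, by = 1 / rate)
  t <- t + rnorm(length(t), sd = 5e-4)
  sort(t[t >= 0 & t < duration])
}

# Inhomogeneous Poisson spike times for one unit: the rate is piecewise
# constant over the partition induced by burst edges and injection times, so
# sampling is exact (Poisson count + uniform placement per segment).
simulate_unit_spikes <- function(rate_base, gain, mults, plan, bursts,
                                 duration, ramp_s = 0) {
  edges <- c(0, duration, plan$inj_s, bursts$start, bursts$end)
  if (ramp_s > 0) {
    for (j in plan$inj_s) {
      edges <- c(edges, seq(j, min(j + ramp_s, duration), by = 1))
    }
  }
  edges <- sort(unique(pmin(pmax(edges, 0), duration)))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mid <- (lo + hi) / 2
  in_burst <- in_intervals(mid, bursts)
  mult <- unname(mults[as.character(period_at(mid, plan))])
  if (ramp_s > 0) {
    # linear onset: interpolate the multiplier over [inj, inj + ramp_s)
    pm <- unname(mults)
    for (j in seq_along(plan$inj_s)) {
      inj <- plan$inj_s[j]
      sel <- mid >= inj & mid < inj + ramp_s
      if (any(sel)) {
        frac <- (mid[sel] - inj) / ramp_s
        mult[sel] <- pm[j] + frac * (pm[j + 1] - pm[j])
      }
    }
  }
  rate <- rate_base * ifelse(in_burst, gain, 1) * mult
  counts <- rpois(length(mid), rate * (hi - lo))
  times <- runif(sum(counts), rep(lo, counts), rep(hi, counts))
  sort(times)
}
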