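#' Stage-level simulation: binned per-unit rate series
#'
#' Draws per-unit 1-s-binned firing rates for every mouse of a cohort from
#' the same inhomogeneous-Poisson rate law as [simulate_recording()], but
#' with no waveform or noise layer: per-bin counts are Poisson with expected
#' value equal to the integral of the rate over the bin (burst overlap and
#' period multipliers included). This is the fast path for validating
#' categorization and decoding stages against planted ground truth.
#'
#' @param config A [sim_config()].
#' @param bin_s Bin width, seconds (default 1).
#' @return A list with `rates` — a tibble with columns `group`, `mouse_id`,
#'   `unit_id`, `bin_start`, `bin_end`, `rate` (CAPs/s), `period`
#'   (`BL`/`C1`/`C2`) and `cytokine` — and `truth` (planted unit table,
#'   per-mouse planted summed rates, burst intervals per mouse).
#' @examples
#' cfg <- make_fixture_config("paper-CON", seed = 1)
#' rs <- simulate_rate_series(cfg)
#' dplyr::count(rs$rates, period)
#' @export
simulate_rate_series <- function(config, bin_s = 1) {
  validate_sim_config(config)
  per_mouse <- lapply(seq_len(config$n_mice), function(m) {
    plan <- config$plans[[m]]
    duration <- plan$total_s
    withr::with_seed(derive_seed(config$seed, m, salt = 2L), {
      bursts <- simulate_bursts(duration, config$resp_burst_duration,
                                config$resp_burst_period)
      edges <- seq(0, duration, by = bin_s)
      lo <- edges[-length(edges)]
      hi <- edges[-1]
      f_burst <- (burst_coverage_at(hi, bursts) -
                    burst_coverage_at(lo, bursts)) / bin_s
      units <- dplyr::filter(config$units, .data$mouse_id == m)
      cyt <- period_cytokine(plan)
      rows <- lapply(seq_len(nrow(units)), function(i) {
        u <- units[i, ]
        mults <- period_multipliers(u$response_c1, u$response_c2)
        # expected count: burst-weighted base rate times the period
        # multiplier averaged over the bin (bins may straddle injections)
        base <- u$baseline_rate * ((1 - f_burst) + u$burst_gain * f_burst)
        w <- period_weights(lo, hi, plan)
        mult_bin <- as.numeric(w %*% unname(mults))
        lambda <- base * mult_bin * bin_s
        tibble::tibble(
          group = config$group_label, mouse_id = m, unit_id = u$unit_id,
          bin_start = lo, bin_end = hi,
          rate = rpois(length(lambda), lambda) / bin_s,
          period = period_at(lo, plan),
          cytokine = dplyr::recode(as.character(period_at(lo, plan)),
                                   BL = "none", !!!as.list(cyt))
        )
      })
      list(rates = dplyr::bind_rows(rows), bursts = bursts)
    })
  })

  units <- config$units
  mice <- units |>
    dplyr::mutate(
      f_BL = .data$overall_rate,
      f_C1 = .data$overall_rate * (1 + .data$response_c1),
      f_C2 = .data$overall_rate * (1 + .data$response_c1) *
        (1 + .data$response_c2)
    ) |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(dplyr::across(c("f_BL", "f_C1", "f_C2"), sum),
                     .groups = "drop")

  list(
    rates = dplyr::bind_rows(lapply(per_mouse, `[[`, "rates")),
    truth = list(units = units, mice = mice,
                 bursts = lapply(per_mouse, `[[`, "bursts"))
  )
}

# Cumulative burst-covered time (s) below each query time.
burst_coverage_at <- function(t, bursts) {
  if (nrow(bursts) == 0) return(rep(0, length(t)))
  len <- bursts$end - bursts$start
  cum <- cumsum(len)
  idx <- findInterval(t, bursts$start)
  out <- numeric(length(t))
  pos <- idx > 0
  i <- idx[pos]
  out[pos] <- cum[i] - len[i] +
    pmin(pmax(t[pos] - bursts$start[i], 0), len[i])
  out
}

# Fraction of each [lo, hi) bin lying in each session period (matrix n x 3).
period_weights <- function(lo, hi, plan) {
  bounds <- c(0, plan$inj_s, plan$total_s)
  w <- sapply(1:3, function(p) {
    pmax(0, pmin(hi, bounds[p + 1]) - pmax(lo, bounds[p])) / (hi - lo)
  })
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  w
}
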