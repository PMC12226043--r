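#' Bin spike times into a labeled rate series
#'
#' @param spike_times Numeric vector of spike times, seconds.
#' @param plan A [session_plan()] supplying period labels.
#' @param bin_s Bin width, seconds (60 for time-series figures, 1 for
#'   decoder features).
#' @param duration Series length, seconds (defaults to the plan's total).
#' @return Tibble with `bin_start`, `bin_end`, `rate` (CAPs/s), `period`
#'   and `cytokine` columns.
#' @export
bin_rates <- function(spike_times, plan, bin_s = 60,
                      duration = plan$total_s) {
  edges <- seq(0, duration, by = bin_s)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  st <- spike_times[spike_times >= 0 & spike_times < duration]
  counts <- tabulate(findInterval(st, edges), nbins = length(edges) - 1)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  cyt <- period_cytokine(plan)
  per <- period_at(lo, plan)
  tibble::tibble(
    bin_start = lo, bin_end = hi,
    rate = counts / (hi - lo),
    period = per,
    cytokine = dplyr::recode(as.character(per), BL = "none", !!!as.list(cyt))
  )
}

#' Baseline firing statistics over the second 10 min of baseline
#'
#' Only the second 10-min baseline window (`[600, 1200)` s by default) is
#' used, to avoid interference from nerve manipulation at the start of a
#' session. The per-mouse statistic is the sum of its units' rates.
#'
#' @param units Tibble with a `unit_id` column, a `spike_times` list-column
#'   (as produced by [sort_recording()]) and optionally `mouse_id`.
#' @param window Length-2 numeric, half-open window in seconds.
#' @param duration Recorded duration, seconds; must cover the window.
#' @return List with `per_unit` (tibble `mouse_id`, `unit_id`, `bl_rate`)
#'   and `per_mouse` (tibble `mouse_id`, `bl_rate_sum`).
#' @export
baseline_stats <- function(units, window = c(600, 1200),
                           duration = max(window)) {
  if (duration < max(window)) {
    stop("session of ", duration, " s is shorter than the baseline window [",
         window[1], ", ", window[2], ")")
  }
  if (!"mouse_id" %in% names(units)) units$mouse_id <- 1L
  per_unit <- units |>
    dplyr::mutate(bl_rate = purrr::map_dbl(
      .data$spike_times,
      ~ sum(.x >= window[1] & .x < window[2]) / diff(window))) |>
    dplyr::select("mouse_id", "unit_id", "bl_rate")
  per_mouse <- per_unit |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(bl_rate_sum = sum(.data$bl_rate), .groups = "drop")
  list(per_unit = per_unit, per_mouse = per_mouse)
}

#' Apply the cytokine-analysis inclusion criteria
#'
#' A unit is excluded when its baseline rate is strictly higher than the
#' cohort mean plus one SD, or when it shows zero firing for more than five
#' consecutive minutes after an injection (i.e. six or more consecutive
#' zero 1-min bins in the post-injection part of the session).
#'
#' @param per_unit Tibble with `unit_id` and `bl_rate` for every candidate
#'   unit of the cohort (the population for the mean + 1 SD rule).
#' @param rates_1min Tibble of 1-min binned rates for the same units
#'   (columns `unit_id`, `bin_start`, `rate`, `period`).
#' @return List with `included` (rows of `per_unit` kept) and `exclusions`
#'   (tibble `unit_id`, `reason`).
#' @export
apply_inclusion <- function(per_unit, rates_1min) {
  thr <- if (nrow(per_unit) > 1) {
    mean(per_unit$bl_rate) + sd(per_unit$bl_rate)
  } else {
    Inf  # a single candidate defines no population spread
  }
  high <- per_unit$bl_rate > thr
  zero_run <- vapply(per_unit$unit_id, function(u) {
    r <- rates_1min |>
      dplyr::filter(.data$unit_id == u, .data$period != "BL") |>
      dplyr::arrange(.data$bin_start)
    if (nrow(r) == 0) return(FALSE)
    z <- rle(r$rate == 0)
    any(z$values & z$lengths >= 6)
  }, logical(1))
  exclusions <- dplyr::bind_rows(
    tibble::tibble(unit_id = per_unit$unit_id[high],
                   reason = "baseline above population mean + 1 SD"),
    tibble::tibble(unit_id = per_unit$unit_id[zero_run & !high],
                   reason = "zero firing > 5 consecutive min post-injection"))
  list(included = per_unit[!(high | zero_run), ], exclusions = exclusions)
}

#' Firing rates inside and outside respiratory bursts
#'
#' @param spike_times Numeric vector, seconds.
#' @param bursts Burst intervals (tibble `start`, `end`).
#' @param duration Session length, seconds.
#' @return Tibble with `burst_rate`, `interburst_rate` (CAPs/s) and the
#'   underlying times and counts.
#' @export
burst_interburst_rates <- function(spike_times, bursts, duration) {
  burst_time <- intervals_total(bursts, duration)
  if (burst_time <= 0) stop("zero total burst time")
  inter_time <- duration - burst_time
  inb <- in_intervals(spike_times, bursts)
  tibble::tibble(
    burst_rate = sum(inb) / burst_time,
    interburst_rate = sum(!inb) / inter_time,
    burst_time_s = burst_time, interburst_time_s = inter_time,
    n_burst = sum(inb), n_interburst = sum(!inb))
}

#' Peri-event histogram of CAPs around burst onsets
#'
#' For each burst onset, spikes within the lag window are accumulated into
#' uniform bins; counts are summed over all supplied spikes (pool units and
#' mice upstream to reproduce group histograms).
#'
#' @param spike_times Numeric vector, seconds.
#' @param onsets Burst onset times, seconds.
#' @param window Lag window `c(lo, hi)`, seconds (default -0.2 to +0.6).
#' @param bin_s Bin width, seconds (default 0.01).
#' @return Tibble of class `cap_peh` with `lag_lo`, `lag_hi`, `lag_mid`
#'   (seconds) and `count`.
#' @export
peri_event_hist <- function(spike_times, onsets, window = c(-0.2, 0.6),
                            bin_s = 0.01) {
  stopifnot(length(onsets) > 0)
  edges <- seq(window[1], window[2], by = bin_s)
  lags <- as.vector(outer(spike_times, onsets, `-`))
  lags <- lags[lags >= window[1] & lags < window[2]]
  counts <- tabulate(findInterval(lags, edges), nbins = length(edges) - 1)
  out <- tibble::tibble(
    lag_lo = edges[-length(edges)], lag_hi = edges[-1],
    lag_mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts)
  class(out) <- c("cap_peh", class(out))
  out
}

#' Normalized cytokine-response ratio
#'
#' `(f_cyt - f_bl) / (f_cyt + f_bl)`, a dimensionless change score in
#' `[-1, 1]`: 0 means no change, +1 firing appearing from silence, negative
#' values decreased firing. Undefined (NA) when both rates are zero.
#'
#' @param f_bl,f_cyt Non-negative rates (CAPs/s); vectorized.
#' @return Numeric vector in `[-1, 1]`, `NA` where both inputs are zero.
#' @examples
#' cytokine_ratio(10, 10)  # 0
#' cytokine_ratio(5, 15)   # 0.5
#' cytokine_ratio(0, 5)    # 1
#' @export
cytokine_ratio <- function(f_bl, f_cyt) {
  stopifnot(all(f_bl >= 0, na.rm = TRUE), all(f_cyt >= 0, na.rm = TRUE))
  out <- (f_cyt - f_bl) / (f_cyt + f_bl)
  out[(f_bl + f_cyt) == 0] <- NA_real_
  out
}

#' Per-mouse cytokine summary (summed rates and ratios)
#'
#' Sums the included units' rates over the last 10 min of baseline and of
#' each cytokine period, and computes the TNF and IL-1beta response ratios.
#'
#' @param rates Tibble of binned rates for one mouse's included units
#'   (columns `unit_id`, `bin_start`, `bin_end`, `rate`, `cytokine`).
#' @param plan The mouse's [session_plan()].
#' @return One-row tibble: `f_BL`, `f_TNF`, `f_IL1`, `ratio_TNF`,
#'   `ratio_IL1`.
#' @export
cytokine_summary <- function(rates, plan) {
  pm <- rates |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(~ period_means(.x, plan)) |>
    dplyr::ungroup() |>
    dplyr::summarise(f_BL = sum(.data$m_BL), f_C1 = sum(.data$m_C1),
                     f_C2 = sum(.data$m_C2))
  cyt <- period_cytokine(plan)
  f <- c(TNF = if (cyt[["C1"]] == "TNF") pm$f_C1 else pm$f_C2,
         IL1B = if (cyt[["C1"]] == "IL1B") pm$f_C1 else pm$f_C2)
  tibble::tibble(
    f_BL = pm$f_BL, f_TNF = f[["TNF"]], f_IL1 = f[["IL1B"]],
    ratio_TNF = cytokine_ratio(pm$f_BL, f[["TNF"]]),
    ratio_IL1 = cytokine_ratio(pm$f_BL, f[["IL1B"]]))
}

#' Mean rate over the last 10 min of each session period
#'
#' Windows are `[600, 1200)`, `[1800, 2400)` and `[3000, 3600)` s for the
#' standard 1-h protocol: the last 10 min of baseline and of each
#' post-injection period.
#'
#' @param rates Tibble of binned rates for one unit (`bin_start`, `bin_end`,
#'   `rate`).
#' @param plan A [session_plan()].
#' @return One-row tibble `m_BL`, `m_C1`, `m_C2` (CAPs/s).
#' @export
period_means <- function(rates, plan) {
  bounds <- c(plan$inj_s[1], plan$inj_s[2], plan$total_s)
  windows <- lapply(bounds, function(b) c(b - 600, b))
  have <- max(rates$bin_end)
  vals <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    if (have < w[2]) {
      stop("session truncated before the ", c("BL", "C1", "C2")[i],
           " window [", w[1], ", ", w[2], ") s")
    }
    ov <- pmax(0, pmin(rates$bin_end, w[2]) - pmax(rates$bin_start, w[1]))
    sum(rates$rate * ov) / sum(ov)
  }, numeric(1))
  tibble::tibble(m_BL = vals[1], m_C1 = vals[2], m_C2 = vals[3])
}

#' Categorize a unit by the signs of its cytokine responses
#'
#' Rate changes are measured against baseline for each post-injection
#' period: `delta_c1 = m_C1 - m_BL`, `delta_c2 = m_C2 - m_BL`. Units
#' increasing to both cytokines are `increasing`, decreasing to both
#' `decreasing`, and opposite signs `mixed`. An exact zero delta is assigned
#' to `mixed` (a measure-zero boundary, reported via a message).
#'
#' @param m_BL,m_C1,m_C2 Period-mean rates (CAPs/s); vectorized.
#' @return Tibble with `delta_c1`, `delta_c2` and `category` (factor
#'   `increasing`/`decreasing`/`mixed`).
#' @examples
#' categorize_unit(5, 8, 9)  # increasing
#' categorize_unit(5, 8, 3)  # mixed
#' @export
categorize_unit <- function(m_BL, m_C1, m_C2) {
  d1 <- m_C1 - m_BL
  d2 <- m_C2 - m_BL
  if (any(d1 == 0 | d2 == 0)) {
    message("exact zero response delta encountered; assigned to 'mixed'")
  }
  cat <- dplyr::case_when(
    d1 > 0 & d2 > 0 ~ "increasing",
    d1 < 0 & d2 < 0 ~ "decreasing",
    TRUE ~ "mixed")
  tibble::tibble(
    delta_c1 = d1, delta_c2 = d2,
    category = factor(cat, levels = c("increasing", "mixed", "decreasing")))
}

#' Category percentages across units
#'
#' @param categories Factor/character vector of unit categories, or a tibble
#'   with a `category` column (and `mouse_id` when `per_mouse = TRUE`).
#' @param per_mouse If `TRUE`, percentages are computed within each mouse.
#' @return Tibble with `category`, `n` and `pct` (percent, rounded to two
#'   decimals, summing to 100 within rounding).
#' @export
category_fractions <- function(categories, per_mouse = FALSE) {
  lv <- c("increasing", "mixed", "decreasing")
  if (!is.data.frame(categories)) {
    categories <- tibble::tibble(category = categories)
  }
  stopifnot(nrow(categories) > 0)
  categories$category <- factor(as.character(categories$category),
                                levels = lv)
  grp <- if (per_mouse) c("mouse_id", "category") else "category"
  categories |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .drop = FALSE) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grp, "category")))) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::ungroup()
}

#' Peak-ordered normalized rate matrix for heatmaps
#'
#' Each unit's rate series is rebinned to `bin_s`, scaled to `[0, 1]` by its
#' own peak firing rate, and rows are ordered by the time of the peak
#' (earliest first; ties broken by unit id; all-zero units last).
#'
#' @param rates Tibble of binned rates for several units (`unit_id`,
#'   `bin_start`, `rate`).
#' @param bin_s Output bin width, seconds (default 10).
#' @return Numeric matrix (units x bins, rownames = unit ids) with
#'   attribute `"order"` (the row order applied) — class `cap_heatmap`.
#' @export
heatmap_matrix <- function(rates, bin_s = 10) {
  stopifnot(nrow(rates) > 0)
  wide <- rates |>
    dplyr::mutate(bin = floor(.data$bin_start / bin_s) * bin_s) |>
    dplyr::group_by(.data$unit_id, .data$bin) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "bin", values_from = "rate",
                       values_fill = 0) |>
    dplyr::arrange(.data$unit_id)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$unit_id
  peak <- apply(m, 1, max)
  norm <- m / ifelse(peak == 0, 1, peak)
  argmax <- apply(norm, 1, which.max)
  argmax[peak == 0] <- ncol(m) + 1L  # all-zero rows placed last
  ord <- order(argmax, rownames(m))
  out <- norm[ord, , drop = FALSE]
  attr(out, "order") <- rownames(m)[ord]
  class(out) <- c("cap_heatmap", class(out))
  out
}

#' Two-group comparison with normality-gated test choice
#'
#' With `test = "auto"`, both samples are checked with the Shapiro-Wilk
#' test at alpha 0.05; if both pass, a two-tailed Student's t-test is used,
#' otherwise the Mann-Whitney U test. The Kolmogorov-Smirnov test is applied
#' only on request (distribution-shape comparisons). Significance threshold
#' for downstream interpretation is P < 0.05.
#'
#' @param sample_a,sample_b Numeric vectors (n >= 3 each).
#' @param test `"auto"`, `"t"`, `"MW"` or `"KS"`.
#' @return One-row tibble: `statistic`, `p_value`, `test`, and the
#'   Shapiro-Wilk p-values when `auto` was used.
#' @export
group_compare <- function(sample_a, sample_b,
                          test = c("auto", "t", "MW", "KS")) {
  test <- match.arg(test)
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("need at least 3 observations per group")
  }
  sw_a <- sw_b <- NA_real_
  if (test == "auto") {
    sw_a <- shapiro.test(sample_a)$p.value
    sw_b <- shapiro.test(sample_b)$p.value
    test <- if (sw_a > 0.05 && sw_b > 0.05) "t" else "MW"
  }
  res <- switch(test,
                t = t.test(sample_a, sample_b),
                MW = suppressWarnings(wilcox.test(sample_a, sample_b)),
                KS = suppressWarnings(ks.test(sample_a, sample_b)))
  tibble::tibble(
    statistic = unname(res$statistic), p_value = res$p.value, test = test,
    shapiro_a = sw_a, shapiro_b = sw_b)
}
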