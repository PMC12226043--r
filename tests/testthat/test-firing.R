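plan <- session_plan()

test_that("rate binning averages counts over bins with period labels", {
  st <- seq(0, 59.5, by = 0.5)  # 2 CAPs/s uniform
  r <- bin_rates(st, plan, bin_s = 1, duration = 60)
  expect_equal(mean(r$rate), 2)
  expect_true(all(r$rate == 2))

  expect_true(all(bin_rates(numeric(0), plan, 60)$rate == 0))

  # spikes only in the first half of one 60-s bin average down by half
  st2 <- seq(0, 29.9, by = 0.1)
  r2 <- bin_rates(st2, plan, bin_s = 60, duration = 60)
  expect_equal(r2$rate[1], length(st2) / 60)

  r3 <- bin_rates(c(100, 1500, 3000), plan, bin_s = 60)
  expect_equal(as.character(r3$period[c(2, 25, 50)]), c("BL", "C1", "C2"))
  expect_equal(r3$cytokine[25], "TNF")
})

test_that("baseline statistics use the second 10-min window and sum per mouse", {
  u <- tibble::tibble(
    mouse_id = c(1, 1, 1),
    unit_id = c("a", "b", "c"),
    spike_times = list(
      c(seq(0, 599.9, by = 0.2), seq(600, 1199.9, by = 0.1)),  # 5 then 10/s
      seq(600, 1199, length.out = 600 * 6),                    # 6/s
      seq(600, 1199, length.out = 600 * 8)                     # 8/s
    ))
  bs <- baseline_stats(u, duration = 1200)
  expect_equal(bs$per_unit$bl_rate[1], 10, tolerance = 1e-3)
  expect_equal(bs$per_mouse$bl_rate_sum, 10 + 6 + 8, tolerance = 0.01)
  expect_error(baseline_stats(u, duration = 900), "shorter")
})

test_that("inclusion criteria follow the mean + 1 SD and zero-run rules", {
  per_unit <- tibble::tibble(unit_id = letters[1:5],
                             bl_rate = c(4, 5, 6, 7, 8.1))
  thr <- mean(per_unit$bl_rate) + sd(per_unit$bl_rate)
  rates <- dplyr::bind_rows(lapply(letters[1:5], function(u) {
    r <- bin_rates(seq(0, 3599, by = 0.5), plan, bin_s = 60)
    r$unit_id <- u
    r
  }))
  # unit e fires above mean + 1 SD only if 8.1 > thr
  res <- apply_inclusion(per_unit, rates)
  expect_identical(res$exclusions$unit_id,
                   per_unit$unit_id[per_unit$bl_rate > thr])

  # six consecutive zero minutes post-injection exclude a unit
  pz <- tibble::tibble(unit_id = c("a", "b", "c"), bl_rate = c(4, 5, 6))
  rz <- dplyr::bind_rows(
    {
      r <- bin_rates(c(seq(0, 1199, by = 0.5), seq(1561, 3599, by = 0.5)),
                     plan, bin_s = 60)
      r$unit_id <- "a"
      r
    },
    dplyr::bind_rows(lapply(c("b", "c"), function(u) {
      r <- bin_rates(seq(0, 3599, by = 0.5), plan, bin_s = 60)
      r$unit_id <- u
      r
    })))
  expect_true(sum(rz$rate[rz$unit_id == "a" & rz$period != "BL"] == 0) >= 6)
  res2 <- apply_inclusion(pz, rz)
  expect_equal(res2$exclusions$unit_id, "a")
  expect_equal(res2$exclusions$reason,
               "zero firing > 5 consecutive min post-injection")

  # exactly mean + 1 SD stays included (strict inequality)
  pu <- tibble::tibble(unit_id = c("a", "b", "c"), bl_rate = c(4, 6, 8))
  thr2 <- mean(pu$bl_rate) + sd(pu$bl_rate)
  pu$bl_rate[3] <- thr2  # would need to exceed, not equal
  r3 <- dplyr::bind_rows(lapply(pu$unit_id, function(u) {
    r <- bin_rates(seq(0, 3599, by = 0.5), plan, bin_s = 60)
    r$unit_id <- u
    r
  }))
  expect_equal(nrow(apply_inclusion(pu, r3)$exclusions), 0)
})

test_that("burst and inter-burst rates partition time and spikes", {
  bursts <- tibble::tibble(start = seq(0, 99, by = 5),
                           end = seq(0, 99, by = 5) + 1)  # 20 % duty
  inside <- as.vector(outer(bursts$start, seq(0.05, 0.95, by = 0.1), `+`))
  r <- burst_interburst_rates(inside, bursts, duration = 100)
  expect_equal(r$burst_rate, length(inside) / 20)
  expect_equal(r$interburst_rate, 0)
  expect_equal(r$burst_time_s + r$interburst_time_s, 100)
  expect_equal(r$n_burst + r$n_interburst, length(inside))

  # homogeneous Poisson: burst and inter-burst rates agree within 2 SE
  withr::with_seed(20, st <- sort(runif(2000, 0, 100)))
  rp <- burst_interburst_rates(st, bursts, 100)
  se <- sqrt(20 / rp$burst_time_s + 20 / rp$interburst_time_s)
  expect_lt(abs(rp$burst_rate - rp$interburst_rate), 2 * se)

  expect_error(burst_interburst_rates(st, bursts[0, ], 100), "burst")
})

test_that("peri-event histograms localize burst-locked firing", {
  onsets <- seq(1, 99, by = 1)
  h <- peri_event_hist(onsets, onsets)  # spikes exactly at onsets
  expect_equal(h$lag_mid[which.max(h$count)], 0.005)
  expect_gte(min(h$count), 0)

  withr::with_seed(21, st <- sort(runif(5000, 0, 100)))
  h2 <- peri_event_hist(st, onsets)
  m <- mean(h2$count)
  expect_lt(max(h2$count), m + 4 * sqrt(m))

  cfg <- toy_config(rates = 6, burst_gain = 4, cardiac_rate = 0, seed = 46)
  rsim <- simulate_recording(cfg, 1, duration_s = 120)
  tb <- rsim$truth$bursts
  h3 <- peri_event_hist(rsim$truth$spikes$time_s, tb$start)
  dur <- mean(tb$end - tb$start)
  inside <- h3$lag_mid > 0 & h3$lag_mid < dur
  before <- h3$lag_mid < 0
  expect_gt(mean(h3$count[inside]), 2 * mean(h3$count[before]))
})

test_that("cytokine ratio arithmetic, bounds and antisymmetry hold", {
  expect_equal(cytokine_ratio(10, 10), 0)
  expect_equal(cytokine_ratio(0, 5), 1)
  expect_equal(cytokine_ratio(5, 15), 0.5)
  expect_true(is.na(cytokine_ratio(0, 0)))
  withr::with_seed(22, {
    a <- runif(200, 0, 50)
    b <- runif(200, 0, 50)
  })
  expect_true(all(abs(cytokine_ratio(a, b)) <= 1))
  expect_equal(cytokine_ratio(a, b), -cytokine_ratio(b, a))
  expect_error(cytokine_ratio(-1, 5))
})

test_that("period means use the last 10 minutes of each period", {
  mk <- function(rates_fun) {
    r <- bin_rates(numeric(0), plan, bin_s = 1)
    r$rate <- rates_fun(r$bin_start)
    r
  }
  expect_equal(unlist(period_means(mk(function(t) rep(5, length(t))), plan)),
               c(m_BL = 5, m_C1 = 5, m_C2 = 5))
  step <- mk(function(t) ifelse(t < 1200, 5, ifelse(t < 2400, 10, 2)))
  expect_equal(unlist(period_means(step, plan)),
               c(m_BL = 5, m_C1 = 10, m_C2 = 2))
  ramp <- mk(function(t) ifelse(t < 1200, 5,
                                ifelse(t < 1800, 2 + t / 1000, 8)))
  expect_equal(period_means(ramp, plan)$m_C1, 8)
  short <- mk(function(t) rep(1, length(t)))
  short <- short[short$bin_start < 2000, ]
  expect_error(period_means(short, plan), "C1|C2")
})

test_that("units are categorized by the sign pattern of their deltas", {
  expect_equal(as.character(categorize_unit(5, 8, 9)$category), "increasing")
  expect_equal(as.character(categorize_unit(5, 3, 2)$category), "decreasing")
  expect_equal(as.character(categorize_unit(5, 8, 3)$category), "mixed")
  expect_message(z <- categorize_unit(5, 5, 7), "zero")
  expect_equal(as.character(z$category), "mixed")
  cu <- categorize_unit(c(5, 5), c(8, 3), c(9, 2))
  expect_equal(cu$delta_c1, c(3, -2))
})

test_that("category fractions reproduce printed percentages and sum to 100", {
  cats <- rep(c("increasing", "mixed", "decreasing"), c(33, 13, 3))
  cf <- category_fractions(cats)
  expect_equal(cf$pct[cf$category == "increasing"], 67.35)
  expect_equal(cf$pct[cf$category == "mixed"], 26.53)
  expect_equal(cf$pct[cf$category == "decreasing"], 6.12)
  expect_lt(abs(sum(cf$pct) - 100), 0.02)

  cf2 <- category_fractions(rep("increasing", 7))
  expect_equal(cf2$pct, c(100, 0, 0))

  per_mouse <- category_fractions(
    tibble::tibble(mouse_id = c(1, 1, 2, 2),
                   category = c("increasing", "mixed", "mixed", "mixed")),
    per_mouse = TRUE)
  expect_equal(per_mouse$pct[per_mouse$mouse_id == 1 &
                               per_mouse$category == "mixed"], 50)
  expect_equal(per_mouse$pct[per_mouse$mouse_id == 2 &
                               per_mouse$category == "mixed"], 100)
})

test_that("heatmap matrix normalizes rows and orders them by peak time", {
  rates <- dplyr::bind_rows(
    tibble::tibble(unit_id = "late", bin_start = seq(0, 3590, by = 10),
                   rate = dnorm(seq(0, 3590, by = 10), 3300, 100)),
    tibble::tibble(unit_id = "early", bin_start = seq(0, 3590, by = 10),
                   rate = dnorm(seq(0, 3590, by = 10), 300, 100)),
    tibble::tibble(unit_id = "flatzero", bin_start = seq(0, 3590, by = 10),
                   rate = 0))
  m <- heatmap_matrix(rates)
  expect_equal(rownames(m), c("early", "late", "flatzero"))
  expect_equal(unname(apply(m[1:2, ], 1, max)), c(1, 1))
  expect_true(all(m["flatzero", ] == 0))

  const <- tibble::tibble(unit_id = "c", bin_start = seq(0, 100, by = 10),
                          rate = 4)
  mc <- heatmap_matrix(const)
  expect_true(all(mc == 1))
})

test_that("group comparison gates the test on Shapiro-Wilk normality", {
  withr::with_seed(23, {
    a <- rnorm(50)
    b <- rnorm(50, 5)
    heavy <- exp(rnorm(50, 0, 1.5))
  })
  res <- group_compare(a, b)
  expect_equal(res$test, "t")
  expect_lt(res$p_value, 1e-6)

  res2 <- group_compare(a, heavy)
  expect_equal(res2$test, "MW")

  same <- c(1.1, 2.2, 3.3, 4.4)
  res3 <- group_compare(same, same, test = "MW")
  expect_equal(res3$p_value, 1, tolerance = 0.05)

  expect_error(group_compare(1:2, 1:5), "at least 3")
  expect_equal(group_compare(a, b, test = "KS")$test, "KS")
})

test_that("cytokine summary computes per-mouse rates and ratios", {
  rates <- dplyr::bind_rows(lapply(c("u1", "u2"), function(u) {
    r <- bin_rates(numeric(0), plan, bin_s = 1)
    r$rate <- ifelse(r$bin_start < 1200, 5,
                     ifelse(r$bin_start < 2400, 15, 5))
    r$unit_id <- u
    r
  }))
  cs <- cytokine_summary(rates, plan)
  expect_equal(cs$f_BL, 10)
  expect_equal(cs$f_TNF, 30)  # C1 = TNF under the default order
  expect_equal(cs$ratio_TNF, 0.5)
  expect_equal(cs$ratio_IL1, 0)
})
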