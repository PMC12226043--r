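fs <- 32000

make_snippets <- function(n_per, templates, noise_sd, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(templates, function(tm) {
      matrix(rep(tm, n_per), nrow = n_per, byrow = TRUE) +
        rnorm(n_per * length(tm), sd = noise_sd)
    }))
  })
}

test_that("t-SNE embedding separates well-spaced templates", {
  t1 <- 40 * dnorm(seq(-3, 3, length.out = 60)) * sqrt(2 * pi)
  t2 <- -35 * dnorm(seq(-1, 5, length.out = 60), 2) * sqrt(2 * pi)
  snip <- make_snippets(100, list(t1, t2), noise_sd = 1, seed = 9)
  emb <- embed_snippets(snip, seed = 1)
  labels <- rep(1:2, each = 100)
  expect_gt(silhouette_score(emb, labels), 0.5)
})

test_that("identical snippets embed as one tight cloud and seeds reproduce", {
  snip <- matrix(rep(sin(seq(0, 3, length.out = 50)), 20), nrow = 20,
                 byrow = TRUE)
  emb <- embed_snippets(snip, seed = 2)
  labs <- cluster_points(emb, eps = 2.5, min_pts = 5)
  expect_lte(max(labs), 1)  # degenerate input fabricates no structure

  expect_identical(embed_snippets(snip, seed = 5),
                   embed_snippets(snip, seed = 5))
  expect_error(embed_snippets(snip[1:5, ]), "at least 10")
})

test_that("DBSCAN clusters blobs, labels sparse scatter noise, handles n = 1", {
  withr::with_seed(10, {
    blobs <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
                   matrix(rnorm(200, 10, 0.1), ncol = 2))
  })
  labs <- cluster_points(blobs, eps = 1, min_pts = 5)
  expect_equal(max(labs), 2)
  expect_equal(sum(labs == 0), 0)
  expect_equal(length(unique(labs[1:100])), 1)

  withr::with_seed(11, sparse <- matrix(runif(60, 0, 100), ncol = 2))
  expect_true(all(cluster_points(sparse, eps = 1e-6, min_pts = 2) == 0))

  expect_equal(cluster_points(matrix(c(0, 0), ncol = 2), eps = 1,
                              min_pts = 1), 1L)
})

test_that("DBSCAN matches brute-force density reachability", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      pts <- rbind(matrix(rnorm(120, 0, 0.5), ncol = 2),
                   matrix(rnorm(120, 4, 0.5), ncol = 2),
                   matrix(runif(60, -4, 8), ncol = 2))
    })
    for (eps in c(0.4, 0.8)) {
      labs <- cluster_points(pts, eps = eps, min_pts = 5)
      expect_dbscan_equiv(labs, oracle_dbscan(pts, eps, 5))
    }
  }
})

test_that("R-peak detection recovers the cardiac rhythm", {
  withr::with_seed(12, {
    ecg <- rnorm(60 * fs, sd = 5)
    tm <- capflow:::make_ecg_template(fs)
    beats <- seq(0.05, 59.95, by = 0.1)
    for (t in beats) {
      c0 <- round(t * fs) + 1
      idx <- (c0 - tm$align + 1):(c0 - tm$align + length(tm$wave))
      ok <- idx >= 1 & idx <= length(ecg)
      ecg[idx[ok]] <- ecg[idx[ok]] + tm$wave[ok]
    }
  })
  peaks <- detect_r_peaks(ecg, fs)
  expect_lt(abs(length(peaks) - 600), 3)
  expect_equal(length(detect_r_peaks(rep(0, fs), fs)), 0)

  cfg <- toy_config(seed = 42)
  sim <- simulate_recording(cfg, 1, duration_s = 60)
  rp <- detect_r_peaks(sim$recording$ecg, fs)
  expect_lt(abs(mean(diff(rp)) - 1 / cfg$cardiac_rate) * cfg$cardiac_rate,
            0.02)
})

test_that("cardiac flag follows the coincidence rule", {
  r_peaks <- seq(0.1, 59.9, by = 0.1)
  expect_true(flag_cardiac(r_peaks + 5e-4, r_peaks))
  expect_false(flag_cardiac(runif(100, 0, 60), numeric(0)))

  # independent Poisson unit vs 10 beats/s: expected coincidence ~ 4 %
  withr::with_seed(13, spikes <- sort(runif(600, 0, 60)))
  expect_false(flag_cardiac(spikes, r_peaks))

  # boundary inclusive: exactly frac coincident flags
  sp <- c(r_peaks[1:80] + 1e-4, seq(0.105, 60, length.out = 20) + 0.011)
  expect_true(flag_cardiac(sp, r_peaks, frac = 0.8))
})

test_that("waveform metrics match closed-form expectations", {
  tri <- c(seq(0, -40, length.out = 20), seq(-40, 60, length.out = 30),
           seq(60, 0, length.out = 20))
  m <- waveform_metrics(tri, fs)
  expect_equal(m$amplitude_uV, 100)

  rect <- c(rep(0, 50), rep(50, round(0.001 * fs)), rep(0, 50))
  expect_equal(waveform_metrics(rect, fs)$width_ms, 1.0, tolerance = 0.05)

  t_ms <- seq(-1.5, 1.5, by = 1000 / fs)
  gauss <- 70 * exp(-t_ms^2 / (2 * 0.2^2))
  fwhm <- 2 * 0.2 * sqrt(2 * log(2))
  expect_equal(waveform_metrics(gauss, fs)$width_ms, fwhm,
               tolerance = 0.02)

  expect_error(waveform_metrics(rep(1, 50), fs), "degenerate")
})

test_that("sort_recording recovers planted units with high agreement", {
  cfg <- toy_config(seed = 43)
  sim <- simulate_recording(cfg, 1, duration_s = 120)
  x <- bandpass(sim$recording$vagus, fs)
  b <- detect_bursts(x, fs)
  thr <- adaptive_threshold(x, b, fs)
  sp <- detect_spikes(x, thr, fs)
  units <- sort_recording(sp, sim$recording$ecg, fs, seed = 1)
  keep <- which(!units$cardiac_flag & !units$unstable_flag)
  expect_equal(length(keep), 3)

  # truth labels for detected events
  tt <- sim$truth$spikes
  lab_truth <- rep("noise", nrow(sp$events))
  for (u in unique(tt$unit_id)) {
    d <- capflow:::nearest_distance(sp$events$time_s,
                                    sort(tt$time_s[tt$unit_id == u]))
    lab_truth[d <= 0.001] <- u
  }
  dc <- capflow:::nearest_distance(sp$events$time_s,
                                   sort(sim$truth$cardiac))
  lab_truth[dc <= 0.0015] <- "cardiac"
  ass <- attr(units, "assignments")
  sel <- lab_truth %in% unique(tt$unit_id) & ass %in% units$unit[keep]
  # best-matching assignment agreement >= 90 %
  tab <- table(lab_truth[sel], ass[sel])
  agreement <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gt(agreement, 0.9)
  # adjusted Rand index vs truth
  expect_gt(adjusted_rand(lab_truth[sel], ass[sel]), 0.9)

  # partition: cluster sizes plus noise account for every detected spike
  expect_equal(sum(units$n_spikes) + sum(ass == 0), nrow(sp$events))

  # amplitude of a noiseless single-unit recording matches the filtered
  # template's peak-to-peak amplitude
  cfg1 <- toy_config(rates = 4, cardiac_rate = 0, noise_sd = 0, seed = 44)
  sim1 <- simulate_recording(cfg1, 1, duration_s = 60)
  x1 <- bandpass(sim1$recording$vagus, fs)
  sp1 <- detect_spikes(x1, 10, fs)
  u1 <- sort_recording(sp1, NULL, fs, min_pts = 5)
  u1 <- u1[which.max(u1$n_spikes), ]
  tm <- capflow:::make_cap_template(fs, cfg1$units$width_factor[1],
                                    cfg1$units$amplitude_uV[1],
                                    cfg1$units$amp_ratio[1])
  v <- rep(0, fs); c0 <- fs / 2
  v[(c0 - tm$align + 1):(c0 - tm$align + length(tm$wave))] <- tm$wave
  ft <- bandpass(v, fs)
  expect_equal(u1$amplitude_uV, max(ft) - min(ft), tolerance = 0.02)
})

test_that("cardiac-only recordings yield only cardiac-flagged clusters", {
  cfg <- toy_config(rates = 1e-9, cardiac_rate = 10, seed = 45)
  sim <- simulate_recording(cfg, 1, duration_s = 60)
  x <- bandpass(sim$recording$vagus, fs)
  b <- detect_bursts(x, fs)
  thr <- adaptive_threshold(x, b, fs)
  sp <- detect_spikes(x, thr, fs)
  units <- sort_recording(sp, sim$recording$ecg, fs, seed = 1)
  expect_true(all(units$cardiac_flag | units$unstable_flag))

  expect_warning(empty <- sort_recording(
    detect_spikes(rep(0, fs), 1, fs), NULL, fs), "no spikes")
  expect_equal(nrow(empty), 0)
  expect_true(isTRUE(attr(empty, "excluded")))
})
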