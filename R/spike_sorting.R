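#' Embed spike snippets in two dimensions with t-SNE
#'
#' Snippets are centered per sample dimension (amplitude information is
#' preserved: per-dimension variance rescaling would down-weight exactly the
#' samples in which distinct CAP waveforms differ), internally reduced to at
#' most 15 principal components, and embedded with t-SNE (Barnes-Hut,
#' perplexity 30 clamped to `(n - 1) / 3` for small inputs). The embedding
#' is deterministic for a fixed seed.
#'
#' @param snippets Numeric matrix, one snippet per row (>= 10 rows).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (clamped for small n).
#' @return Numeric n x 2 matrix of embedded coordinates.
#' @export
embed_snippets <- function(snippets, seed = 1L, perplexity = 30) {
  snippets <- as.matrix(snippets)
  n <- nrow(snippets)
  if (n < 10) {
    stop("need at least 10 snippets to embed; with fewer spikes assign ",
         "them to templates directly")
  }
  z <- scale(snippets, scale = FALSE)
  perp <- min(perplexity, floor((n - 1) / 3))
  withr::with_seed(derive_seed(seed, 0L, salt = 5L), {
    # tiny deterministic dither keeps duplicate snippets embeddable
    z <- z + matrix(rnorm(length(z), sd = 1e-8), nrow = n)
    Rtsne::Rtsne(z, dims = 2, perplexity = max(1, perp), pca = TRUE,
                 initial_dims = min(15L, ncol(z)), check_duplicates = FALSE,
                 max_iter = 500, verbose = FALSE)$Y
  })
}

#' Detect R-peaks on the ECG channel
#'
#' Deflections exceeding 5 times the robust noise SD (either polarity) are
#' grouped within a 50-ms refractory window and aligned at the absolute
#' extremum.
#'
#' @param ecg ECG signal, uV.
#' @param fs Sampling rate, samples/s.
#' @param mult Threshold multiplier on the robust SD.
#' @param refractory_ms Refractory window, ms.
#' @return Numeric vector of R-peak times, seconds.
#' @export
detect_r_peaks <- function(ecg, fs, mult = 5, refractory_ms = 50) {
  if (length(ecg) == 0 || all(ecg == 0)) return(numeric(0))
  thr <- mult * robust_sd(ecg)
  if (thr <= 0) return(numeric(0))
  gap <- max(1L, round(refractory_ms / 1000 * fs))
  idx <- detect_events_cpp(ecg, rep(thr, length(ecg)), gap)
  (idx - 1) / fs
}

#' Flag a cluster as cardiac by ECG coincidence
#'
#' A sorted cluster is cardiac if at least `frac` (boundary inclusive) of
#' its spikes fall within `tol_ms` of an R-peak. For independent Poisson
#' firing the expected coincidence fraction is about `2 * tol * heart_rate`
#' (~4 % at defaults), so genuine CAP units are essentially never flagged.
#'
#' @param spike_times Numeric vector, seconds.
#' @param r_peaks Sorted R-peak times from [detect_r_peaks()].
#' @param tol_ms Coincidence tolerance, ms.
#' @param frac Minimum coincident fraction.
#' @return Logical scalar; `FALSE` when `r_peaks` is empty.
#' @export
flag_cardiac <- function(spike_times, r_peaks, tol_ms = 2.0, frac = 0.8) {
  if (length(r_peaks) == 0 || length(spike_times) == 0) return(FALSE)
  hit <- nearest_distance(spike_times, sort(r_peaks)) <= tol_ms / 1000
  mean(hit) >= frac
}

#' Waveform metrics of a sorted unit
#'
#' Computed on the mean waveform: peak-to-peak amplitude (max minus min) and
#' half-height width — the time span, linearly interpolated at the
#' crossings, over which the dominant phase (the larger-magnitude excursion,
#' relative to a zero baseline) exceeds half its peak.
#'
#' @param snippets Matrix of snippets (rows) or a single waveform vector.
#' @param fs Sampling rate, samples/s.
#' @return Tibble with `amplitude_uV` and `width_ms`.
#' @examples
#' fs <- 32000
#' t_ms <- seq(-1.5, 1.5, by = 1000 / fs)
#' w <- 60 * exp(-t_ms^2 / (2 * 0.2^2))  # Gaussian, FWHM = 0.2 * 2.355 ms
#' waveform_metrics(w, fs)
#' @export
waveform_metrics <- function(snippets, fs) {
  w <- if (is.matrix(snippets)) colMeans(snippets) else as.numeric(snippets)
  if (max(w) == min(w)) stop("degenerate waveform: flat mean waveform")
  amp <- max(w) - min(w)
  i_peak <- which.max(abs(w))
  y <- w * sign(w[i_peak])     # dominant phase pointing up
  half <- y[i_peak] / 2
  lo <- i_peak
  while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
  hi <- i_peak
  n <- length(y)
  while (hi < n && y[hi + 1] >= half) hi <- hi + 1
  left <- if (lo > 1) lo - (y[lo] - half) / (y[lo] - y[lo - 1]) else lo
  right <- if (hi < n) hi + (y[hi] - half) / (y[hi] - y[hi + 1]) else hi
  tibble::tibble(amplitude_uV = amp, width_ms = (right - left) / fs * 1000)
}

#' Sort detected spikes into CAP units
#'
#' Full sorting chain: embed snippets with t-SNE ([embed_snippets()]),
#' cluster the embedding with DBSCAN ([cluster_points()]), compute per-unit
#' mean waveforms and metrics, and flag cardiac clusters by ECG coincidence
#' ([flag_cardiac()]). Cardiac-flagged clusters are retained in the output
#' but marked for exclusion from firing analysis.
#'
#' For recordings with more than `max_embed` spikes a seeded subsample is
#' embedded and clustered; the remaining snippets are then assigned to the
#' nearest cluster centroid in principal-component space (distance-capped,
#' so outliers stay noise). Quality screening merges near-identical
#' clusters, dissolves unstable/minority/noise-floor clusters (cardiac
#' clusters are exempt so they stay visible and flagged), and prunes
#' threshold-grazing noise events from each cluster.
#'
#' @param spikes A `cap_spikes` object from [detect_spikes()].
#' @param ecg ECG signal (uV) for cardiac flagging, or `NULL` to skip.
#' @param fs Sampling rate, samples/s.
#' @param eps,min_pts DBSCAN parameters (embedded units).
#' @param max_embed Maximum number of snippets embedded directly.
#' @param seed Integer seed.
#' @param cardiac_frac Coincidence fraction passed to [flag_cardiac()];
#'   the pipeline default (0.6) is laxer than the rule's own default
#'   because CAP/cardiac collision events dilute cardiac clusters.
#' @return Tibble with one row per unit: `unit`, `n_spikes`,
#'   `amplitude_uV`, `width_ms`, `cardiac_flag`, `unstable_flag` (waveform
#'   too variable to be a single fiber population; exclude from analysis
#'   like cardiac clusters), and list-columns `spike_times`,
#'   `mean_waveform`, `sem_waveform`. The integer spike->unit
#'   assignment (0 = noise) is attached as attribute `"assignments"`; if no
#'   spikes were detected the result has zero rows and attribute
#'   `"excluded"` is `TRUE` (recordings without spikes are excluded from
#'   analysis).
#' @export
sort_recording <- function(spikes, ecg, fs, eps = 2.5, min_pts = 10,
                           max_embed = 1200, seed = 1L,
                           cardiac_frac = 0.6) {
  n <- nrow(spikes$events)
  empty <- tibble::tibble(
    unit = integer(0), n_spikes = integer(0), amplitude_uV = numeric(0),
    width_ms = numeric(0), cardiac_flag = logical(0),
    spike_times = list(), mean_waveform = list(), sem_waveform = list())
  if (n == 0) {
    warning("no spikes detected; recording excluded from analysis")
    attr(empty, "excluded") <- TRUE
    return(empty)
  }

  # cluster on the central +-0.75 ms of each snippet: the full 3-ms window
  # is kept for waveform metrics, but its flanks mostly carry neighboring
  # events, which would blur the embedding
  core <- central_window(spikes$snippets, spikes$fs, core_ms = 1.5)
  feats <- snippet_features(core)
  sub <- if (n > max_embed) {
    withr::with_seed(derive_seed(seed, 1L, salt = 6L),
                     sort(sample.int(n, max_embed)))
  } else {
    seq_len(n)
  }
  emb <- embed_snippets(core[sub, , drop = FALSE], seed = seed)
  sub_labels <- cluster_points(emb, eps = eps, min_pts = min_pts)

  labels <- integer(n)
  labels[sub] <- sub_labels
  k <- max(sub_labels)
  if (k > 0 && length(sub) < n) {
    centroids <- vapply(seq_len(k), function(cl) {
      colMeans(feats[sub[sub_labels == cl], , drop = FALSE])
    }, numeric(ncol(feats)))
    radius <- vapply(seq_len(k), function(cl) {
      member <- feats[sub[sub_labels == cl], , drop = FALSE]
      d <- sqrt(rowSums((member - matrix(centroids[, cl], nrow(member),
                                         ncol(feats), byrow = TRUE))^2))
      stats::quantile(d, 0.995) * 1.5
    }, numeric(1))
    rest <- setdiff(seq_len(n), sub)
    d2 <- vapply(seq_len(k), function(cl) {
      rowSums((feats[rest, , drop = FALSE] -
                 matrix(centroids[, cl], length(rest), ncol(feats),
                        byrow = TRUE))^2)
    }, numeric(length(rest)))
    d2 <- matrix(d2, nrow = length(rest))
    best <- max.col(-d2, ties.method = "first")
    ok <- sqrt(d2[cbind(seq_along(rest), best)]) <= radius[best]
    labels[rest[ok]] <- best[ok]
  }

  if (k == 0) {
    warning("no clusters found; all spikes labeled noise")
    attr(empty, "assignments") <- labels
    return(empty)
  }

  labels <- merge_similar_clusters(spikes$snippets, labels)
  r_peaks <- if (is.null(ecg)) numeric(0) else detect_r_peaks(ecg, fs)
  # cardiac clusters are exempt from quality screening: their members are
  # heavily contaminated by CAP collisions, but they must stay visible in
  # the output (flagged, excluded from analysis) rather than dissolve
  protected <- vapply(sort(unique(labels[labels > 0])), function(cl) {
    flag_cardiac(spikes$events$time_s[labels == cl], r_peaks,
                 frac = cardiac_frac)
  }, logical(1))
  labels <- dissolve_minor_clusters(core, feats, labels,
                                    snippets = spikes$snippets,
                                    protected = protected)
  # amplitude pruning: threshold-grazing noise events reassigned into a
  # cluster carry a far smaller extremum than the cluster's CAPs
  center_amp <- abs(spikes$snippets[, spikes$half + 1L])
  for (cl in seq_len(max(labels))) {
    sel <- labels == cl
    if (any(sel)) {
      labels[sel & center_amp < 0.45 * median(center_amp[sel])] <- 0L
    }
  }
  k <- max(labels)
  if (k == 0) {
    warning("no clusters survived quality screening")
    attr(empty, "assignments") <- labels
    return(empty)
  }
  units <- purrr::map_dfr(seq_len(k), function(cl) {
    sel <- labels == cl
    snip <- spikes$snippets[sel, , drop = FALSE]
    mw <- colMeans(snip)
    sdd <- apply(snip, 2, sd)
    # robust within-cluster waveform spread: high in every sample only when
    # members are systematically contaminated (overlap/collision clusters),
    # not when a minority of snippets carries a neighboring spike
    mad_ratio <- mean(apply(snip, 2, stats::mad)) /
      (max(mw) - min(mw) + .Machine$double.eps)
    met <- waveform_metrics(snip, fs)
    times <- spikes$events$time_s[sel]
    tibble::tibble(
      unit = cl, n_spikes = sum(sel),
      amplitude_uV = met$amplitude_uV, width_ms = met$width_ms,
      cardiac_flag = flag_cardiac(times, r_peaks, frac = cardiac_frac),
      unstable_flag = mad_ratio > 0.08,
      spike_times = list(times), mean_waveform = list(mw),
      sem_waveform = list(sdd / sqrt(sum(sel))))
  })
  attr(units, "assignments") <- labels
  units
}

# Merge clusters whose mean waveforms are near-identical (cosine similarity
# > 0.95, RMS difference < 15 % of the larger peak-to-peak amplitude, and
# amplitudes within 25 % of each other). Such splits arise from sub-sample
# alignment jitter or noise-regime differences, not from distinct fiber
# populations, whose filtered waveforms are far less similar.
merge_similar_clusters <- function(snippets, labels, cos_min = 0.95,
                                   rel_max = 0.15) {
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2) break
    mw <- vapply(ids, function(cl) colMeans(snippets[labels == cl, ,
                                                     drop = FALSE]),
                 numeric(ncol(snippets)))
    p2p <- apply(mw, 2, function(w) max(w) - min(w))
    merged <- FALSE
    for (a in seq_along(ids)[-length(ids)]) {
      for (b in seq((a + 1), length(ids))) {
        cs <- sum(mw[, a] * mw[, b]) /
          sqrt(sum(mw[, a]^2) * sum(mw[, b]^2))
        rel <- sqrt(mean((mw[, a] - mw[, b])^2)) / max(p2p[a], p2p[b])
        amp_ok <- min(p2p[a], p2p[b]) / max(p2p[a], p2p[b]) > 0.8
        if (cs > cos_min && rel < rel_max && amp_ok) {
          labels[labels == ids[b]] <- ids[a]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # compact labels to 1..k preserving first-appearance order of cluster ids
  ids <- sort(unique(labels[labels > 0]))
  labels[labels > 0] <- match(labels[labels > 0], ids)
  labels
}

central_window <- function(snippets, fs, core_ms = 1.5) {
  center <- (ncol(snippets) + 1L) %/% 2L
  half <- min(center - 1L, round(core_ms / 2 / 1000 * fs))
  snippets[, (center - half):(center + half), drop = FALSE]
}

# Quality screening: clusters that are either waveform-unstable (robust
# within-cluster spread above 8 % of the peak-to-peak amplitude, i.e.
# overlap/collision artifacts) or minor (below `minor_frac` of assigned
# spikes, typically noise or fragment clusters) are dissolved: their spikes
# are reassigned to the nearest surviving cluster centroid (within its
# radius) or labeled noise.
dissolve_minor_clusters <- function(core, feats, labels, minor_frac = 0.02,
                                    mad_max = 0.08, snippets = core,
                                    protected = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 2) return(labels)
  if (is.null(protected)) protected <- rep(FALSE, length(ids))
  n_assigned <- sum(labels > 0)
  flank_cols <- c(seq_len(min(8, ncol(snippets))),
                  seq(max(1, ncol(snippets) - 7), ncol(snippets)))
  stats <- vapply(ids, function(cl) {
    snip <- core[labels == cl, , drop = FALSE]
    mw <- colMeans(snip)
    mad_ratio <- mean(apply(snip, 2, stats::mad)) /
      (max(mw) - min(mw) + .Machine$double.eps)
    # a genuine unit's mean waveform must rise well above the noise floor
    # estimated from the snippet flanks; incoherent mixtures average out
    flank_sd <- median(abs(snippets[labels == cl, flank_cols])) / 0.6745
    c(n = nrow(snip), mad_ratio = mad_ratio,
      snr_ok = max(abs(mw)) >= 5 * flank_sd)
  }, numeric(3))
  major <- protected |
    (stats["n", ] / n_assigned >= minor_frac &
       stats["mad_ratio", ] <= mad_max &
       stats["snr_ok", ] > 0)
  if (!any(major) || all(major)) {
    if (!any(major)) return(labels)
    ids_major <- ids[major]
  } else {
    ids_major <- ids[major]
  }
  minor_sel <- labels > 0 & !(labels %in% ids_major)
  if (any(minor_sel)) {
    centroids <- vapply(ids_major, function(cl) {
      colMeans(feats[labels == cl, , drop = FALSE])
    }, numeric(ncol(feats)))
    radius <- vapply(seq_along(ids_major), function(j) {
      member <- feats[labels == ids_major[j], , drop = FALSE]
      d <- sqrt(rowSums((member - matrix(centroids[, j], nrow(member),
                                         ncol(feats), byrow = TRUE))^2))
      stats::quantile(d, 0.995) * 1.5
    }, numeric(1))
    fm <- feats[minor_sel, , drop = FALSE]
    d2 <- vapply(seq_along(ids_major), function(j) {
      rowSums((fm - matrix(centroids[, j], nrow(fm), ncol(feats),
                           byrow = TRUE))^2)
    }, numeric(nrow(fm)))
    d2 <- matrix(d2, nrow = nrow(fm))
    best <- max.col(-d2, ties.method = "first")
    ok <- sqrt(d2[cbind(seq_len(nrow(fm)), best)]) <= radius[best]
    new_lab <- ifelse(ok, ids_major[best], 0L)
    labels[minor_sel] <- new_lab
  }
  ids2 <- sort(unique(labels[labels > 0]))
  labels[labels > 0] <- match(labels[labels > 0], ids2)
  labels
}

# Centered PCA features (<= 15 dims) used for centroid assignment.
snippet_features <- function(snippets) {
  z <- scale(snippets, scale = FALSE)
  k <- min(15L, ncol(z), nrow(z))
  p <- prcomp(z, rank. = k, center = FALSE)
  p$x
}
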