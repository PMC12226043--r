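#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass (default 160-3000 Hz, the passband used
#' for cuff CAP recordings), applied forward and backward for zero phase
#' distortion. The filter is applied to an odd-reflection-padded copy of the
#' signal so edges are well behaved; output length equals input length.
#'
#' @param x Numeric signal, uV.
#' @param fs Sampling rate, samples/s.
#' @param low,high Band edges, Hz.
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 32000
#' t <- seq(0, 0.1, by = 1 / fs)
#' x <- sin(2 * pi * 1000 * t) + 100  # 1 kHz tone on a DC offset
#' y <- bandpass(x, fs)
#' c(mean(y), max(abs(y)))  # DC removed, tone preserved
#' @export
bandpass <- function(x, fs, low = 160, high = 3000) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) {
    stop("high cutoff ", high, " Hz reaches the Nyquist frequency of fs = ",
         fs, " samples/s")
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  filtfilt_fast(bf$b, bf$a, x)
}

# Forward-backward IIR filtering with odd-reflection padding (pad length
# 3 x filter order on each side), direct-form-II core in C++.
filtfilt_fast <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[seq(pad + 1, pad + n)]
}

#' Detect respiratory bursts from a filtered signal
#'
#' Respiratory bursts are recurring windows of elevated background noise and
#' vagal firing. They are detected from a robust amplitude envelope: the
#' median of `|x|` over a sliding window (default 20 ms, evaluated on a 5-ms
#' grid). A median envelope tracks the noise floor itself and is inherently
#' insensitive to isolated large deflections (CAPs, cardiac artifacts),
#' which occupy only a small fraction of any window; only a sustained rise
#' of the background marks a burst. Samples where the envelope exceeds `k`
#' times its session-wide median are burst candidates; candidate intervals
#' separated by gaps shorter than `merge_gap_ms` are merged and intervals
#' shorter than `min_dur_ms` discarded.
#'
#' @param x Band-pass-filtered signal, uV.
#' @param fs Sampling rate, samples/s.
#' @param window_ms Envelope window, ms.
#' @param k Threshold multiplier on the median envelope.
#' @param merge_gap_ms,min_dur_ms Post-processing parameters, ms.
#' @return Tibble of half-open intervals (`start`, `end`; seconds), sorted
#'   and non-overlapping. A flat signal yields zero rows.
#' @export
detect_bursts <- function(x, fs, window_ms = 20, k = 2,
                          merge_gap_ms = 30, min_dur_ms = 40) {
  n <- length(x)
  chunk_len <- max(2L, round(5 / 1000 * fs))     # 5-ms evaluation grid
  cm <- chunk_median_abs_cpp(x, rep(FALSE, n), chunk_len)[, 2]
  kk <- 2L * max(1L, round(window_ms / 5 / 2)) + 1L
  env <- if (length(cm) > kk) {
    stats::runmed(cm, kk, endrule = "median")
  } else {
    rep(median(cm), length(cm))
  }
  med <- median(cm)
  above <- env > k * med
  if (!any(above)) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  iv <- tibble::tibble(
    start = (starts_idx[r$values] - 1) * chunk_len / fs,
    end = pmin(ends_idx[r$values] * chunk_len, n) / fs)
  iv <- merge_close_intervals(iv, merge_gap_ms / 1000)
  iv[iv$end - iv$start >= min_dur_ms / 1000, ]
}

merge_close_intervals <- function(iv, gap_s) {
  if (nrow(iv) <= 1) return(iv)
  grp <- cumsum(c(TRUE, iv$start[-1] - iv$end[-nrow(iv)] >= gap_s))
  tibble::tibble(start = as.numeric(tapply(iv$start, grp, min)),
                 end = as.numeric(tapply(iv$end, grp, max)))
}

#' Burst-aware adaptive detection threshold
#'
#' Returns one threshold value per sample: `m` times a robust noise SD
#' (median absolute deviation scaled by 1/0.6745) estimated separately for
#' samples inside and outside respiratory bursts, over a sliding ~1-s window
#' restricted to the current regime. The threshold therefore rises during
#' bursts whenever the burst noise is higher, which is what lets spike
#' detection run at a constant effective false-positive rate across the
#' respiratory cycle.
#'
#' @param x Band-pass-filtered signal, uV.
#' @param bursts Burst intervals from [detect_bursts()] (tibble
#'   `start`/`end`, seconds).
#' @param fs Sampling rate, samples/s.
#' @param m Threshold multiplier (default 4).
#' @param window_s Sliding estimation window, seconds.
#' @param pad_ms Dilation applied to the burst intervals (ms) so that the
#'   noisier in-burst regime, not the quiet baseline, governs the threshold
#'   across the burst onset/offset transitions.
#' @return Numeric vector of thresholds, same length as `x`.
#' @export
adaptive_threshold <- function(x, bursts, fs, m = 4, window_s = 1,
                               pad_ms = 10) {
  n <- length(x)
  chunk_len <- max(16L, round(fs * window_s / 4))
  padded <- if (nrow(bursts) > 0) {
    merge_close_intervals(tibble::tibble(
      start = pmax(bursts$start - pad_ms / 1000, 0),
      end = bursts$end + pad_ms / 1000), 0)
  } else {
    bursts
  }
  mask <- intervals_to_mask(padded, n, fs)
  med <- chunk_median_abs_cpp(x, mask, chunk_len)
  half_w <- 2L  # +-2 chunks ~ 1-s window
  sd_in <- smooth_regime_sd(med[, 1], half_w) / 0.6745
  sd_out <- smooth_regime_sd(med[, 2], half_w) / 0.6745
  per_in <- rep(sd_in, each = chunk_len)[seq_len(n)]
  thr <- rep(sd_out, each = chunk_len)[seq_len(n)]
  thr[mask] <- per_in[mask]
  m * thr
}

# Rolling median over chunk-level estimates, then interpolation across
# chunks where the regime is absent.
smooth_regime_sd <- function(s, half_w) {
  k <- length(s)
  out <- vapply(seq_len(k), function(i) {
    win <- s[max(1, i - half_w):min(k, i + half_w)]
    if (all(is.na(win))) NA_real_ else median(win, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (length(ok) == 0) return(rep(0, k))
    out <- approx(ok, out[ok], xout = seq_len(k), rule = 2)$y
  }
  out
}

#' Detect spikes by adaptive threshold crossing
#'
#' Threshold crossings of either polarity are grouped: supra-threshold
#' samples closer than the refractory window belong to one event, aligned at
#' the absolute extremum (ties resolved to the earliest sample). A fixed-
#' length waveform snippet centered on the alignment sample is cut for each
#' event; events too close to the signal edges for a full snippet are
#' dropped.
#'
#' @param x Band-pass-filtered signal, uV.
#' @param threshold Per-sample threshold from [adaptive_threshold()] (or a
#'   scalar, recycled).
#' @param fs Sampling rate, samples/s.
#' @param snippet_ms Snippet length, ms (centered; actual length is the odd
#'   sample count nearest `snippet_ms * fs / 1000`).
#' @param refractory_ms Grouping window, ms.
#' @param shadow_ms,shadow_frac Echo suppression: an event whose extremum is
#'   below `shadow_frac` times that of a larger event within `shadow_ms` is
#'   discarded as a residual lobe (filter ringing) of that larger event
#'   rather than an independent CAP. Set `shadow_frac = 0` to disable.
#' @return A `cap_spikes` object: list with `events` (tibble `time_s`,
#'   `polarity`) and `snippets` (events x samples matrix, uV), plus `fs` and
#'   the snippet half-width.
#' @export
detect_spikes <- function(x, threshold, fs, snippet_ms = 3.0,
                          refractory_ms = 1.0, shadow_ms = 12.0,
                          shadow_frac = 0.3) {
  n <- length(x)
  if (length(threshold) == 1) threshold <- rep(threshold, n)
  stopifnot(length(threshold) == n)
  gap <- max(1L, round(refractory_ms / 1000 * fs))
  idx <- detect_events_cpp(x, threshold, gap)
  idx <- suppress_echoes(idx, abs(x[idx]), round(shadow_ms / 1000 * fs),
                         shadow_frac)
  half <- max(1L, round(snippet_ms / 2 / 1000 * fs))
  idx <- idx[idx > half & idx + half <= n]
  snippets <- if (length(idx) > 0) {
    x[outer(idx, (-half):half, `+`)]
  } else {
    matrix(numeric(0), 0, 2 * half + 1)
  }
  dim(snippets) <- c(length(idx), 2L * half + 1L)
  structure(list(
    events = tibble::tibble(time_s = (idx - 1) / fs,
                            polarity = sign(x[idx])),
    snippets = snippets,
    fs = fs,
    half = half
  ), class = "cap_spikes")
}

# Drop events dominated by a larger neighbor (residual filter lobes).
# Events are sorted in time; only a handful of neighbors can fall inside the
# shadow window thanks to the refractory grouping.
suppress_echoes <- function(idx, amp, window, frac) {
  n <- length(idx)
  if (n < 2 || frac <= 0) return(idx)
  drop <- logical(n)
  for (j in seq_len(n)) {
    k <- j - 1L
    while (k >= 1L && idx[j] - idx[k] <= window) {
      if (amp[j] <= frac * amp[k]) { drop[j] <- TRUE; break }
      k <- k - 1L
    }
    if (drop[j]) next
    k <- j + 1L
    while (k <= n && idx[k] - idx[j] <= window) {
      if (amp[j] <= frac * amp[k]) { drop[j] <- TRUE; break }
      k <- k + 1L
    }
  }
  idx[!drop]
}

#' @export
print.cap_spikes <- function(x, ...) {
  cat(sprintf("<cap_spikes> %d events, snippets %d samples at %d Hz\n",
              nrow(x$events), ncol(x$snippets), x$fs))
  invisible(x)
}
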