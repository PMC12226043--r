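# Shared internal helpers: interval arithmetic on half-open [start, end)
# windows (seconds) and deterministic seed derivation.

# Derive a per-mouse / per-stage RNG seed below 2^31 from a user seed.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) * 7919 + index * 104729 + salt * 15485863
  as.integer(s %% 2147483647) + 1L
}

# Logical mask (one element per sample) marking samples inside any interval.
intervals_to_mask <- function(intervals, n, fs) {
  mask <- logical(n)
  if (is.null(intervals) || nrow(intervals) == 0) return(mask)
  lo <- pmax(1L, floor(intervals$start * fs) + 1L)
  hi <- pmin(n, ceiling(intervals$end * fs))
  for (i in seq_along(lo)) if (hi[i] >= lo[i]) mask[lo[i]:hi[i]] <- TRUE
  mask
}

# Total time (s) covered by a set of disjoint intervals, clipped to [0, dur).
intervals_total <- function(intervals, duration) {
  if (nrow(intervals) == 0) return(0)
  sum(pmax(0, pmin(intervals$end, duration) - pmax(intervals$start, 0)))
}

# TRUE for each time falling inside any half-open interval.
in_intervals <- function(times, intervals) {
  if (nrow(intervals) == 0 || length(times) == 0) {
    return(logical(length(times)))
  }
  idx <- findInterval(times, intervals$start)
  idx > 0 & times < intervals$end[pmax(idx, 1L)]
}

# Overlap (s) of one query window [lo, hi) with a set of disjoint intervals.
interval_overlap <- function(lo, hi, intervals) {
  if (nrow(intervals) == 0) return(rep(0, length(lo)))
  vapply(seq_along(lo), function(i) {
    sum(pmax(0, pmin(intervals$end, hi[i]) - pmax(intervals$start, lo[i])))
  }, numeric(1))
}

# Robust noise SD: median absolute deviation from zero, Gaussian-consistent.
robust_sd <- function(x) median(abs(x)) / 0.6745

# Distance (s) from each time to the nearest element of a sorted reference.
nearest_distance <- function(times, ref) {
  if (length(ref) == 0) return(rep(Inf, length(times)))
  idx <- findInterval(times, ref)
  lo <- ifelse(idx >= 1, ref[pmax(idx, 1L)], -Inf)
  hi <- ifelse(idx < length(ref), ref[pmin(idx + 1L, length(ref))], Inf)
  pmin(times - lo, hi - times)
}
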