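# Independent oracle implementations used to validate the fast paths.

# Brute-force spike detection: scan every sample, collect local maxima of
# |x| above threshold, group candidates lying within the refractory window
# of the running group extremum, then apply echo suppression by exhaustive
# pairwise comparison. Pure R, O(n^2) in events.
oracle_detect <- function(x, thr, fs, refractory_ms = 1, shadow_ms = 12,
                          shadow_frac = 0.3) {
  n <- length(x)
  if (length(thr) == 1) thr <- rep(thr, n)
  gap <- round(refractory_ms / 1000 * fs)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (abs(x[i]) > thr[i]) {
      l <- if (i > 1) abs(x[i - 1]) else -Inf
      r <- if (i < n) abs(x[i + 1]) else -Inf
      if (abs(x[i]) >= l && abs(x[i]) >= r) cand <- c(cand, i)
    }
  }
  events <- integer(0)
  best <- NA_integer_
  for (i in cand) {
    if (is.na(best)) {
      best <- i
    } else if (i - best <= gap) {
      if (abs(x[i]) > abs(x[best])) best <- i
    } else {
      events <- c(events, best)
      best <- i
    }
  }
  if (!is.na(best)) events <- c(events, best)
  win <- round(shadow_ms / 1000 * fs)
  keep <- rep(TRUE, length(events))
  for (a in seq_along(events)) {
    for (b in seq_along(events)) {
      if (a != b && abs(events[a] - events[b]) <= win &&
          abs(x[events[a]]) <= shadow_frac * abs(x[events[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  events[keep]
}

# Brute-force DBSCAN by explicit density-reachability closure on the full
# adjacency matrix. Returns core labels, the noise set, and for each border
# point the set of clusters that could legally claim it.
oracle_dbscan <- function(pts, eps, min_pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  adj <- as.matrix(stats::dist(pts)) <= eps
  diag(adj) <- TRUE
  core <- rowSums(adj) >= min_pts
  cc <- adj & outer(core, core)
  repeat {
    nxt <- cc | ((cc %*% cc) > 0)
    if (all(nxt == cc)) break
    cc <- nxt
  }
  labels <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] == 0L) {
      cl <- cl + 1L
      comp <- which(cc[i, ] & core)
      labels[union(comp, i)] <- cl
    }
  }
  border_opts <- lapply(seq_len(n), function(j) {
    if (core[j]) return(labels[j])
    opts <- unique(labels[adj[j, ] & core])
    opts[opts > 0]
  })
  list(core_labels = ifelse(core, labels, 0L), core = core,
       border_opts = border_opts)
}

# Check a DBSCAN labeling against the oracle: core points must partition
# identically (up to relabeling), noise must be exactly the points with no
# core neighbor, and every border point must carry a label from its legal
# option set (or 0 only if it has no options).
expect_dbscan_equiv <- function(labels, oracle) {
  core <- oracle$core
  # bijection between label sets on core points
  tab <- table(labels[core], oracle$core_labels[core])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  for (j in which(!core)) {
    opts <- oracle$border_opts[[j]]
    if (length(opts) == 0) {
      expect_identical(labels[j], 0L)
    } else {
      expect_true(labels[j] != 0L)
      # the claimed cluster must map to one of the oracle's legal clusters
      mapped <- unique(oracle$core_labels[core][labels[core] == labels[j]])
      expect_true(any(mapped %in% opts))
    }
  }
}

# Mean silhouette of a labeled 2-D embedding (simple O(n^2) version).
silhouette_score <- function(pts, labels) {
  d <- as.matrix(stats::dist(pts))
  vals <- vapply(seq_len(nrow(pts)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(pts)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(vals)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
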