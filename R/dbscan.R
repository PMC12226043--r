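#' Density-based clustering (DBSCAN) of embedded points
#'
#' Classic DBSCAN: a point with at least `min_pts` neighbors within `eps`
#' (itself included) is a core point; clusters are the connected components
#' of core points under eps-reachability, plus border points attached to the
#' first cluster that reaches them. Remaining points are labeled noise (0).
#'
#' @param points Numeric matrix (n x 2, or any dimension).
#' @param eps Neighborhood radius (> 0).
#' @param min_pts Minimum neighborhood size for a core point (>= 1).
#' @return Integer vector of cluster labels (1, 2, ...; 0 = noise).
#' @examples
#' pts <- rbind(matrix(rnorm(100, 0, .1), ncol = 2),
#'              matrix(rnorm(100, 10, .1), ncol = 2))
#' table(cluster_points(pts, eps = 1, min_pts = 5))
#' @export
cluster_points <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d2 <- as.matrix(stats::dist(points))^2
  eps2 <- eps^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- lengths(nbr) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    qi <- 1L
    while (qi <= length(queue)) {
      j <- queue[[qi]]
      qi <- qi + 1L
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}
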