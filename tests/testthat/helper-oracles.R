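# Independent oracles used to cross-check package computations. These are
# deliberately naive (O(n^2) scans, hand Dijkstra) and share no code with
# the implementation paths they verify.

# longest shortest path over the 8-neighbour pixel graph of a mask,
# unit weight for orthogonal steps and sqrt(2) for diagonal steps
oracle_geodesic_diameter <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n <= 1) return(0)
  w <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(px[i, 1] - px[j, 1]); dc <- abs(px[i, 2] - px[j, 2])
    if (i != j && dr <= 1 && dc <= 1)
      w[i, j] <- if (dr + dc == 2) sqrt(2) else 1
  }
  best <- 0
  for (src in seq_len(n)) {
    dist <- rep(Inf, n); dist[src] <- 0; done <- rep(FALSE, n)
    for (k in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      relax <- which(is.finite(w[u, ]))
      dist[relax] <- pmin(dist[relax], dist[u] + w[u, relax])
    }
    best <- max(best, max(dist[is.finite(dist)]))
  }
  best
}

# distinct reads overlapping each exon by >= 1 base, by direct scan
oracle_overlap_counts <- function(exons, reads) {
  vapply(seq_len(nrow(exons)), function(i) {
    hit <- reads$start < exons$end[i] & reads$end > exons$start[i]
    length(unique(reads$read_id[hit]))
  }, integer(1))
}

# Pearson correlation from the textbook formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# two-sided binomial-CI half width (percent scale) for a PSI estimate
binom_ci_half <- function(psi_pct, n, level = 0.99) {
  p <- psi_pct / 100
  100 * qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
}

# random cluster-size partition summing to n (used for droplet scenes)
random_cluster_sizes <- function(n, seed) {
  set.seed(seed)
  cs <- integer(0); left <- n
  while (left > 0) {
    k <- min(sample(1:3, 1), left)
    cs <- c(cs, k); left <- left - k
  }
  cs
}
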