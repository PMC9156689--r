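# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Brute-force conditional two-sided p-value for the NB exact test: builds
# the conditional distribution of the group-A total from explicit dnbinom
# products at an arbitrary mean (the conditional law is mean-free, so any
# mu > 0 gives the same answer), then sums minimum-likelihood mass.
oracle_nb_exact_p <- function(s_a, t, n_a, n_b, dispersion, mu = 7.3) {
  a <- 0:t
  if (dispersion == 0) {
    mass <- dpois(a, n_a * mu) * dpois(t - a, n_b * mu)
  } else {
    r <- 1 / dispersion
    mass <- dnbinom(a, size = n_a * r, mu = n_a * mu) *
      dnbinom(t - a, size = n_b * r, mu = n_b * mu)
  }
  mass <- mass / sum(mass)
  sum(mass[mass <= mass[s_a + 1] * (1 + 1e-8)])
}

# Exhaustive 2-cluster 1-D k-means: tries every assignment of points into
# two non-empty groups (no contiguity assumption) and returns the minimal
# within-cluster sum of squares.
oracle_kmeans2_sse <- function(x) {
  n <- length(x)
  best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    sse <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    if (sse < best) best <- sse
  }
  best
}

# Base-pair level interval overlap, the slow route for the cis/trans rule.
oracle_overlaps_bp <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq(a_start, a_end), seq(b_start, b_end))) >= 1
}

# Step-up BH computed from its closed form (m * p_(i) / i with a running
# minimum from the largest p down), independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

tiny_rpm <- function(mat, samples = NULL) {
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(mat),
                          genotype_id = colnames(mat),
                          stringsAsFactors = FALSE)
  }
  rpm_normalize(count_matrix(mat, samples))
}
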