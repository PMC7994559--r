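options(spikeshift.log_level = "NONE")

# bins x samples matrix -> bin_matrix over a single toy chromosome
toy_bins <- function(counts, width = 10000, chrom = "chrT") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }
  g <- genome_index(setNames(nrow(counts) * width, chrom))
  bin_matrix(bin_genome(g, width), counts)
}

# Exhaustive-threshold oracle for the two-sample KS statistic.
oracle_ks_D <- function(a, b) {
  thresholds <- sort(unique(c(a, b)))
  max(vapply(thresholds, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Exact hypergeometric upper-tail by direct enumeration of the 2x2 tables.
oracle_hyper_p <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force TMM-on-spikes oracle: explicit M/A enumeration, order-based
# trimming, explicit weighted mean; independent of the package's code path.
oracle_cnn_factors <- function(spikes, N,
                               logratio_trim = 0.3, abundance_trim = 0.05) {
  uq <- apply(spikes, 2, function(x) quantile(x, 0.75)) / N
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(spikes)), function(j) {
    obs <- spikes[, j]; rf <- spikes[, ref]
    ok <- obs > 0 & rf > 0
    obs <- obs[ok]; rf <- rf[ok]
    M <- log2(obs / N[j]) - log2(rf / N[ref])
    A <- (log2(obs / N[j]) + log2(rf / N[ref])) / 2
    w <- 1 / ((N[j] - obs) / (N[j] * obs) + (N[ref] - rf) / (N[ref] * rf))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    loA <- floor(n * abundance_trim) + 1
    keepM <- order(M)[loM:(n + 1 - loM)]
    keepA <- order(A)[loA:(n + 1 - loA)]
    keep <- intersect(keepM, keepA)
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

jaccard_1d <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  union <- max(a_end, b_end) - min(a_start, b_start)
  inter / union
}
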