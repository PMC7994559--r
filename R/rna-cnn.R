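#' Cell-number normalization factors from spike-in rows
#'
#' Computes per-sample normalization factors by the trimmed-mean-of-M-values
#' scheme applied to the spike-in rows only, with library sizes fixed to the
#' gene-count column sums `N` (not the spike totals).  Because the spikes
#' were added per cell equivalent, a factor below 1 means the sample's
#' endogenous transcriptome is larger per cell than the reference's - the
#' quantity per-library normalization cannot see.
#'
#' The reference sample is the one whose upper-quartile spike expression
#' (relative to `N`) is closest to the mean across samples.  For every other
#' sample, per-spike log2 ratios (M) and average log2 abundances (A) against
#' the reference are formed, the most extreme 30% of M and 5% of A are
#' trimmed, and the factor is `2^` the inverse-asymptotic-variance weighted
#' mean of the surviving M values.  Factors are centered to geometric mean 1.
#'
#' @param counts a `ss_count_matrix` with at least one flagged spike row.
#' @param logratio_trim,abundance_trim trim fractions for M and A.
#' @return a `cnn_factors` data frame: `sample`, `nf`, `lib_size` (N),
#'   `effective_size` (N x nf); the reference sample as attribute.
#' @export
cnn_norm_factors <- function(counts, logratio_trim = 0.3,
                             abundance_trim = 0.05) {
  assert_that(ncol(counts$counts) >= 2, "need at least 2 samples")
  assert_that(sum(counts$is_spike) > 0, "no spike rows flagged",
              "spikeshift_degenerate_error")
  spikes <- counts$counts[counts$is_spike, , drop = FALSE]
  genes <- counts$counts[!counts$is_spike, , drop = FALSE]
  N <- colSums(genes)
  spike_tot <- colSums(spikes)
  assert_that(all(spike_tot > 0),
              sprintf("sample with all-zero spikes: %s",
                      colnames(spikes)[which(spike_tot == 0)[1]]),
              "spikeshift_degenerate_error")
  # reference: upper-quartile spike expression closest to the mean
  uq <- apply(spikes, 2, quantile, probs = 0.75) / N
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(spikes)), function(j) {
    tmm_pair_factor(spikes[, j], spikes[, ref], N[j], N[ref],
                    logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / geometric_mean(f)
  out <- data.frame(sample = colnames(spikes), nf = f, lib_size = N,
                    effective_size = N * f, row.names = NULL)
  attr(out, "reference") <- colnames(spikes)[ref]
  class(out) <- c("cnn_factors", "data.frame")
  ss_log("cnn_norm_factors: %d spikes, ref %s, nf %s", nrow(spikes),
         colnames(spikes)[ref], paste(sprintf("%.3f", f), collapse = ", "))
  out
}

# Trimmed, weighted mean of per-spike M values for one sample against the
# reference.  obs/ref are spike counts; n_obs/n_ref the gene-count library
# sizes the rates are formed against.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, abundance_trim = 0.05) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic variance of M for binomial counts
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Cell-number-normalized log2 expression
#'
#' The voom-style transformation with effective library sizes `N x nf`:
#' `log2((count + prior) / (N * nf + 1) * 1e6)`.  Monotone in the count;
#' spike rows are excluded from the output.
#'
#' @param counts a `ss_count_matrix`.
#' @param factors a `cnn_factors` data frame covering all samples (from
#'   [cnn_norm_factors()]); any data frame with `sample` and
#'   `effective_size` columns works.
#' @param prior prior count added before the log (default 0.5).
#' @return genes x samples numeric matrix of CNN log2 expression.
#' @export
cnn_log_expression <- function(counts, factors, prior = 0.5) {
  m <- counts$counts[!counts$is_spike, , drop = FALSE]
  idx <- match(colnames(m), factors$sample)
  assert_that(!anyNA(idx),
              sprintf("no factor for sample: %s",
                      colnames(m)[which(is.na(idx))[1]]),
              "spikeshift_lookup_error")
  eff <- factors$effective_size[idx]
  log2(t(t(m + prior) / (eff + 1)) * 1e6)
}
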