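#' Per-bin enrichment distribution
#'
#' Averages replicate columns of the scaled IP and input bin matrices, then
#' computes per bin `log2(IP/input + pseudocount)`.  Bins with zero input
#' cannot form a ratio; they are dropped and tallied.  The value list is
#' what cumulative-enrichment (ECDF) plots and KS comparisons consume.
#'
#' @param ip_bins,input_bins [bin_matrix()] objects over identical bins
#'   (scaled counts); all columns of each are treated as replicates and
#'   averaged before the ratio.
#' @param pseudocount added to the IP/input ratio before log2 (default 0.5,
#'   so a zero-IP bin maps to -1).
#' @param label optional sample/condition label carried along.
#' @return an `ss_enrichment` list: `values`, `label`, `pseudocount`,
#'   `n_dropped`.
#' @export
enrichment_distribution <- function(ip_bins, input_bins, pseudocount = 0.5,
                                    label = NULL) {
  assert_that(same_bins(ip_bins, input_bins),
              "IP and input bin lists differ", "spikeshift_alignment_error")
  ip <- rowMeans(ip_bins$counts)
  inp <- rowMeans(input_bins$counts)
  ok <- inp > 0
  values <- log2(ip[ok] / inp[ok] + pseudocount)
  ss_log("enrichment_distribution: %d bins, %d dropped (zero input)",
         length(ip), sum(!ok))
  structure(list(values = unname(values), label = label,
                 pseudocount = pseudocount, n_dropped = sum(!ok)),
            class = "ss_enrichment")
}

#' Two-sample Kolmogorov-Smirnov comparison of enrichment distributions
#'
#' Two-sided two-sample KS test of the per-bin enrichment values; `D` is the
#' maximum gap between the two ECDFs and `p` the asymptotic two-sided
#' p-value.  Symmetric in its arguments.
#'
#' @param a,b `ss_enrichment` objects (or bare numeric vectors).
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  va <- if (inherits(a, "ss_enrichment")) a$values else as.numeric(a)
  vb <- if (inherits(b, "ss_enrichment")) b$values else as.numeric(b)
  assert_that(length(va) > 0 && length(vb) > 0,
              "empty enrichment distribution", "spikeshift_degenerate_error")
  kt <- suppressWarnings(ks.test(va, vb, alternative = "two.sided",
                                 exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(va), n_b = length(vb))
}

#' ECDF evaluator for an enrichment distribution
#'
#' @param x an `ss_enrichment`.
#' @return a step function, as [stats::ecdf()].
#' @export
enrichment_ecdf <- function(x) {
  assert_that(inherits(x, "ss_enrichment"), "need an ss_enrichment")
  ecdf(x$values)
}
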