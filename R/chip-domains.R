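#' Call broad enrichment domains from binned counts
#'
#' A simplified broad-domain caller: per bin, a one-sided Poisson upper-tail
#' test of the (replicate-averaged) IP count against an expected count
#' derived from the matched input, followed by Benjamini-Hochberg control
#' across bins and chaining of significant bins into domains allowing gaps
#' of up to `gap_bins` non-significant bins.
#'
#' The expected count is, per bin, the maximum of the bin-level input, the
#' input smoothed with a running mean of `background_window` bins and the
#' chromosome-wide mean, rescaled to the IP total (the local-lambda
#' convention of peak callers).  Taking the maximum biases the expectation
#' upward, which keeps the test conservative even though the input is
#' itself a noisy counted sample.
#'
#' @param ip_bins,input_bins [bin_matrix()] objects over identical bins
#'   (scaled counts); columns are averaged.
#' @param gap_bins maximum run of non-significant bins bridged inside a
#'   domain (default 3).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param background_window width (bins) of the input smoothing window.
#' @return an [intervals()] data frame of domains.
#' @export
call_broad_domains <- function(ip_bins, input_bins, gap_bins = 3,
                               q_threshold = 0.05, background_window = 51) {
  assert_that(same_bins(ip_bins, input_bins),
              "IP and input bin lists differ", "spikeshift_alignment_error")
  ip <- rowMeans(ip_bins$counts)
  inp <- rowMeans(input_bins$counts)
  assert_that(sum(inp) > 0, "all-zero input", "spikeshift_degenerate_error")
  chrom <- ip_bins$bins$chrom
  scale <- sum(ip) / sum(inp)
  lambda <- unlist(lapply(split(seq_along(inp), factor(chrom, unique(chrom))),
                          function(idx) {
    pmax(inp[idx], running_mean(inp[idx], background_window),
         mean(inp[idx])) * scale
  }))
  lambda <- pmax(lambda, .Machine$double.eps)
  p <- ppois(ceiling(ip) - 1, lambda, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  sig <- padj < q_threshold
  ss_log("call_broad_domains: %d bins, %d significant at q<%g",
         length(sig), sum(sig), q_threshold)
  if (!any(sig)) return(intervals(character(), numeric(), numeric()))
  doms <- lapply(split(seq_along(sig), factor(chrom, unique(chrom))),
                 function(idx) {
    hits <- idx[sig[idx]]
    if (length(hits) == 0) return(NULL)
    # new domain when the gap to the previous significant bin exceeds gap_bins
    brk <- c(TRUE, diff(hits) - 1 > gap_bins)
    grp <- cumsum(brk)
    first <- tapply(hits, grp, min)
    last <- tapply(hits, grp, max)
    data.frame(chrom = chrom[first],
               start = ip_bins$bins$start[first],
               end = ip_bins$bins$end[last])
  })
  doms <- do.call(rbind, doms[!vapply(doms, is.null, logical(1))])
  intervals(doms$chrom, doms$start, doms$end)
}

running_mean <- function(x, window) {
  if (window <= 1 || length(x) == 1) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Merge nearby peaks within replicates and intersect across them
#'
#' Within each replicate, intervals separated by a gap of at most
#' `merge_distance` bases are merged (a gap of exactly `merge_distance`
#' merges, matching `bedtools merge -d`); the result is the set of regions
#' present in both merged replicates (`bedtools intersect` semantics).
#' Idempotent and order-invariant; output is sorted and disjoint.
#'
#' @param peaks_rep1,peaks_rep2 [intervals()] data frames.
#' @param merge_distance maximum gap merged within a replicate (default
#'   3 kb).
#' @return an [intervals()] data frame of common regions.
#' @export
merge_and_intersect <- function(peaks_rep1, peaks_rep2,
                                merge_distance = 3000) {
  merged <- function(x) {
    if (nrow(x) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(as_granges(x),
                          min.gapwidth = merge_distance + 1,
                          ignore.strand = TRUE)
  }
  common <- GenomicRanges::intersect(merged(peaks_rep1), merged(peaks_rep2),
                                     ignore.strand = TRUE)
  common <- GenomicRanges::sort(common)
  if (length(common) == 0) return(intervals(character(), numeric(), numeric()))
  from_granges(common)
}
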