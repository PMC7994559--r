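#' Spike-in normalization factor for one IP sample
#'
#' The normalization factor (NF) is the ratio of target/spike read counts in
#' the IP taken as a fraction of the same ratio in its matched input:
#' \deqn{NF = (t_{IP}/s_{IP}) / (t_{input}/s_{input})}
#' It is dimensionless, invariant to uniform depth rescaling of either
#' sample, and equals 1 when the IP enriches target over spike no more than
#' the input does.  Because the spike chromatin is constant per cell, the
#' NF tracks true per-cell signal mass across conditions.
#'
#' @param ip,matched_input one-row data frames (or lists) with fields
#'   `target_reads`, `spike_reads` and optionally `role`.
#' @return a one-row data frame with `sample` (if present) and `nf`.
#' @export
#' @examples
#' compute_spikein_nf(list(target_reads = 900000, spike_reads = 100000),
#'                    list(target_reads = 800000, spike_reads = 200000))
compute_spikein_nf <- function(ip, matched_input) {
  for (x in list(ip, matched_input)) {
    assert_that(x$target_reads > 0 && x$spike_reads > 0,
                "NF undefined: zero target or spike reads",
                "spikeshift_degenerate_error")
  }
  if (!is.null(ip$role)) {
    assert_that(ip$role == "IP" && matched_input$role == "input",
                "arguments must be an IP and its matched input, in that order")
  }
  nf <- (ip$target_reads / ip$spike_reads) /
    (matched_input$target_reads / matched_input$spike_reads)
  data.frame(sample = if (is.null(ip$sample)) NA_character_ else ip$sample,
             nf = nf)
}

#' Spike-in NFs for a whole sample sheet
#'
#' Pairs each IP row of a species-split count table with the input row of
#' the same condition and replicate and computes per-sample NFs.
#'
#' @param species_counts data frame with columns sample, role, condition,
#'   replicate, target_reads, spike_reads.
#' @return data frame: sample, condition, replicate, nf.
#' @export
compute_spikein_nfs <- function(species_counts) {
  ips <- species_counts[species_counts$role == "IP", , drop = FALSE]
  inputs <- species_counts[species_counts$role == "input", , drop = FALSE]
  key <- function(df) paste(df$condition, df$replicate)
  idx <- match(key(ips), key(inputs))
  assert_that(!anyNA(idx), "every IP needs a matched input",
              "spikeshift_lookup_error")
  nf <- vapply(seq_len(nrow(ips)), function(i) {
    compute_spikein_nf(ips[i, ], inputs[idx[i], ])$nf
  }, numeric(1))
  out <- data.frame(sample = ips$sample, condition = ips$condition,
                    replicate = ips$replicate, nf = nf)
  ss_log("compute_spikein_nfs: %d IP samples, NFs %s", nrow(out),
         paste(sprintf("%.3f", nf), collapse = ", "))
  out
}

#' Tile a genome with uniform bins
#'
#' Per chromosome, half-open bins `[0,w), [w,2w), ...`; the last bin is
#' truncated at the chromosome end.  The bins are pairwise disjoint and
#' their union is the genome.
#'
#' @param genome a [genome_index()].
#' @param width bin width in bases (default 10 kb).
#' @return an [intervals()] data frame.
#' @export
bin_genome <- function(genome, width = 10000) {
  assert_that(width > 0, "width must be positive")
  pieces <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + width, len))
  })
  df <- do.call(rbind, pieces)
  intervals(df$chrom, df$start, df$end)
}

#' Apply spike-in scale factors to binned counts
#'
#' Multiplies each sample column by its NF; with `depth_normalize = TRUE`
#' counts are first converted to per-million of the sample's target-genome
#' depth.  The composite factor is recorded in `scale_applied`.
#'
#' @param bins a [bin_matrix()].
#' @param factors data frame with columns `sample` and `nf` (from
#'   [compute_spikein_nfs()]), covering every sample in `bins`.
#' @param depth_normalize divide by (target depth / 1e6) first.
#' @param depths named vector of per-sample target-genome depths; defaults
#'   to column sums when `depth_normalize` is on.
#' @return a scaled [bin_matrix()].
#' @export
scale_bin_counts <- function(bins, factors, depth_normalize = FALSE,
                             depths = NULL) {
  samples <- colnames(bins$counts)
  idx <- match(samples, factors$sample)
  assert_that(!anyNA(idx),
              sprintf("no scale factor for sample: %s",
                      samples[which(is.na(idx))[1]]),
              "spikeshift_lookup_error")
  nf <- factors$nf[idx]
  composite <- nf
  if (depth_normalize) {
    if (is.null(depths)) depths <- colSums(bins$counts)
    assert_that(all(samples %in% names(depths)),
                "depths must cover every sample", "spikeshift_lookup_error")
    composite <- nf / (depths[samples] / 1e6)
  }
  composite <- unname(composite)
  scaled <- sweep(bins$counts, 2, composite, `*`)
  ss_log("scale_bin_counts: %d bins x %d samples, factors %s",
         nrow(scaled), ncol(scaled),
         paste(sprintf("%.3f", composite), collapse = ", "))
  bin_matrix(bins$bins, scaled,
             scale_applied = setNames(bins$scale_applied[samples] * composite,
                                      samples))
}
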