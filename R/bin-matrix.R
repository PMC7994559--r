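#' Binned count matrices
#'
#' A `bin_matrix` couples a set of uniform, non-overlapping genomic bins with
#' a bins x samples matrix of (raw or scaled) counts, and records the
#' composite scale factor already applied to each sample column.
#'
#' @param bins an [intervals()] data frame of non-overlapping, sorted bins.
#' @param counts numeric matrix, `nrow(counts) == nrow(bins)`, with sample
#'   names as column names; values must be non-negative.
#' @param scale_applied named numeric vector of per-sample factors already
#'   applied (1 for raw counts).
#' @return an object of class `ss_bin_matrix`.
#' @export
bin_matrix <- function(bins, counts, scale_applied = NULL) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == nrow(bins),
              "counts rows must match number of bins",
              "spikeshift_alignment_error")
  assert_that(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
              "counts must have unique sample column names",
              "spikeshift_format_error")
  assert_that(all(counts >= 0), "negative counts", "spikeshift_format_error")
  if (is.null(scale_applied)) {
    scale_applied <- setNames(rep(1, ncol(counts)), colnames(counts))
  }
  assert_that(all(colnames(counts) %in% names(scale_applied)),
              "scale_applied must cover every sample",
              "spikeshift_lookup_error")
  structure(
    list(bins = bins, counts = counts,
         scale_applied = scale_applied[colnames(counts)]),
    class = "ss_bin_matrix"
  )
}

#' @export
print.ss_bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d bins x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(head(colnames(x$counts), 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ss_bin_matrix <- function(x) dim(x$counts)

same_bins <- function(a, b) {
  isTRUE(all.equal(a$bins$chrom, b$bins$chrom)) &&
    isTRUE(all.equal(a$bins$start, b$bins$start)) &&
    isTRUE(all.equal(a$bins$end, b$bins$end))
}
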