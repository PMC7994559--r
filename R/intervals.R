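#' Genomic intervals and genome indices
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `name`, `score`, `strand`.  Coordinates are 0-based half-open
#' everywhere inside the package (the BED convention); conversion to the
#' 1-based closed convention of GenomicRanges happens only at the boundary
#' helpers below.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name,score,strand optional annotation columns; `strand` defaults
#'   to `"."` (unstranded).
#' @return a data.frame of class `c("ss_intervals", "data.frame")`.
#' @export
#' @examples
#' intervals("chr1", 0, 100)
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, strand = ".") {
  if (length(chrom) == 0) {
    name <- character(); score <- numeric(); strand <- character()
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("ss_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  assert_that(all(df$end > df$start),
              "interval with start >= end (empty or inverted)",
              "spikeshift_format_error")
  assert_that(all(df$start >= 0), "negative start coordinate",
              "spikeshift_format_error")
  assert_that(all(df$strand %in% c("+", "-", ".")),
              "strand must be one of '+', '-', '.'",
              "spikeshift_format_error")
  invisible(df)
}

#' @rdname intervals
#' @param genome named numeric vector or list, chromosome name -> length.
#' @export
genome_index <- function(genome) {
  genome <- unlist(genome)
  lens <- as.numeric(genome)
  nms <- names(genome)
  assert_that(!is.null(nms) && all(nzchar(nms)), "chromosome names required",
              "spikeshift_format_error")
  assert_that(!anyDuplicated(nms), "duplicate chromosome names",
              "spikeshift_format_error")
  assert_that(all(lens > 0) && all(lens == round(lens)),
              "chromosome lengths must be positive integers",
              "spikeshift_format_error")
  structure(setNames(lens, nms), class = "ss_genome")
}

# ss_intervals (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df, genome = NULL) {
  seqlen <- NULL
  if (!is.null(genome)) seqlen <- setNames(as.integer(genome), names(genome))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand),
    seqlengths = seqlen
  )
}

# GRanges -> ss_intervals
from_granges <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand
  )
}
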