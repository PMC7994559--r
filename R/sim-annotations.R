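#' Simulate genome annotation fixtures
#'
#' Generates the annotation inputs the region-level analyses consume: a set
#' of strand-labelled single-base TSS records, a set of non-overlapping
#' repeat elements with family names, and named gene sets drawn from a
#' simulated gene universe.  All draws are reproducible from `seed`.
#'
#' @param genome a [genome_index()].
#' @param n_tss number of TSS records.
#' @param n_repeats number of repeat elements.
#' @param gene_sets named integer vector: set name -> size.
#' @param universe_size size of the simulated gene universe the sets are
#'   drawn from (default 2000).
#' @param repeat_width_range min/max repeat element width in bases.
#' @param seed integer seed.
#' @return list with `tss` (intervals, names = gene ids), `repeats`
#'   (intervals with family names), `gene_sets` (named list of character
#'   vectors) and `universe` (character vector).
#' @export
simulate_annotations <- function(genome, n_tss = 100, n_repeats = 100,
                                 gene_sets = NULL, universe_size = 2000,
                                 repeat_width_range = c(200, 2000),
                                 seed = 1) {
  assert_that(length(genome) > 0, "genome must be non-empty")
  total <- sum(genome)
  assert_that(n_tss <= total, "more TSSs requested than bases available")
  universe <- sprintf("gene%05d", seq_len(universe_size))
  if (!is.null(gene_sets)) {
    assert_that(all(gene_sets <= universe_size),
                "gene set larger than the universe")
  }
  with_seed(seed, {
    # TSSs: uniform positions across chromosomes, random strands
    chrom_pick <- sample(names(genome), n_tss, replace = TRUE,
                         prob = genome / total)
    pos <- floor(runif(n_tss) * (genome[chrom_pick] - 1))
    tss <- intervals(chrom_pick, pos, pos + 1,
                     name = universe[seq_len(min(n_tss, universe_size))],
                     strand = sample(c("+", "-"), n_tss, replace = TRUE))

    # repeats: greedy non-overlapping placement on the largest chromosome
    chr <- names(genome)[which.max(genome)]
    chr_len <- genome[[chr]]
    widths <- floor(runif(n_repeats * 4, repeat_width_range[1],
                          repeat_width_range[2] + 1))
    starts <- sort(floor(runif(n_repeats * 4) * (chr_len - max(widths))))
    keep_start <- numeric(0); keep_width <- numeric(0); last_end <- -1
    for (i in seq_along(starts)) {
      if (starts[i] > last_end) {
        keep_start <- c(keep_start, starts[i])
        keep_width <- c(keep_width, widths[i])
        last_end <- starts[i] + widths[i]
      }
      if (length(keep_start) == n_repeats) break
    }
    assert_that(length(keep_start) == n_repeats,
                "requested repeats exceed genome capacity")
    fams <- c("LINE", "SINE", "LTR", "Satellite")
    repeats <- intervals(chr, keep_start, keep_start + keep_width,
                         name = sprintf("%s_%04d",
                                        sample(fams, n_repeats, replace = TRUE),
                                        seq_len(n_repeats)))

    sets <- list()
    if (!is.null(gene_sets)) {
      for (nm in names(gene_sets)) {
        sets[[nm]] <- sample(universe, gene_sets[[nm]])
      }
    }
    list(tss = tss, repeats = repeats, gene_sets = sets, universe = universe)
  })
}
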