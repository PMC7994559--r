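#' Quantify signal over regions
#'
#' Per region and sample, sums the overlapping bin signal with bins weighted
#' by their overlap fraction, so a region covering half a bin receives half
#' that bin's value and a tiling of the genome conserves the total signal.
#' Optional normalization by spike-in factors or library size, division by a
#' matched input, and replicate averaging.
#'
#' @param signal a [bin_matrix()].
#' @param regions an [intervals()] data frame; every chromosome must be
#'   present in the bins.
#' @param normalization `"none"`, `"spike_nf"` (multiply by per-sample NF)
#'   or `"library_size"` (counts per million of the column total).
#' @param factors data frame `sample`, `nf` (required for `"spike_nf"`).
#' @param input optional matched input [bin_matrix()]; region values are
#'   divided by the input's region values (same normalization applied to the
#'   input's library size where relevant); zero-input regions give `NA`.
#' @param average_replicates average sample columns into one column per
#'   replicate group.
#' @param replicate_groups named character vector sample -> group (defaults
#'   to sample names stripped of a trailing `_rep<k>` tag).
#' @return a regions x samples numeric matrix; region names (or
#'   `chrom:start-end`) as row names.
#' @export
region_counts <- function(signal, regions, normalization = c("none",
                            "spike_nf", "library_size"),
                          factors = NULL, input = NULL,
                          average_replicates = FALSE,
                          replicate_groups = NULL) {
  normalization <- match.arg(normalization)
  bin_chroms <- unique(signal$bins$chrom)
  bad <- setdiff(unique(regions$chrom), bin_chroms)
  assert_that(length(bad) == 0,
              sprintf("region on unknown chromosome: %s", bad[1]),
              "spikeshift_lookup_error")
  m <- region_overlap_sums(signal, regions)
  m <- apply_region_norm(m, signal, normalization, factors)
  if (!is.null(input)) {
    mi <- region_overlap_sums(input, regions)
    if (normalization == "library_size") {
      mi <- apply_region_norm(mi, input, "library_size", NULL)
    }
    ipool <- rowMeans(mi)
    m <- m / ifelse(ipool > 0, ipool, NA_real_)
  }
  if (average_replicates) {
    if (is.null(replicate_groups)) {
      replicate_groups <- setNames(sub("_rep[0-9]+", "", colnames(m)),
                                   colnames(m))
    }
    grp <- replicate_groups[colnames(m)]
    groups <- unique(grp)
    m <- matrix(vapply(groups, function(g)
      rowMeans(m[, grp == g, drop = FALSE]), numeric(nrow(m))),
      nrow = nrow(m), dimnames = list(NULL, groups))
  }
  rn <- ifelse(is.na(regions$name),
               sprintf("%s:%s-%s", regions$chrom,
                       format_coord(regions$start), format_coord(regions$end)),
               regions$name)
  rownames(m) <- make.unique(rn)
  m
}

region_overlap_sums <- function(signal, regions) {
  gr_bins <- as_granges(signal$bins)
  gr_reg <- as_granges(regions)
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_bins, ignore.strand = TRUE)
  out <- matrix(0, nrow(regions), ncol(signal$counts),
                dimnames = list(NULL, colnames(signal$counts)))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_reg[qh], gr_bins[sh],
                                  ignore.strand = TRUE)
  frac <- GenomicRanges::width(ov) / GenomicRanges::width(gr_bins[sh])
  w <- signal$counts[sh, , drop = FALSE] * frac
  for (j in seq_len(ncol(out))) {
    out[, j] <- as.numeric(tapply(w[, j], factor(qh, seq_len(nrow(regions))),
                                  sum, default = 0))
  }
  out
}

apply_region_norm <- function(m, signal, normalization, factors) {
  if (normalization == "spike_nf") {
    assert_that(!is.null(factors), "spike_nf normalization needs factors",
                "spikeshift_lookup_error")
    idx <- match(colnames(m), factors$sample)
    assert_that(!anyNA(idx),
                sprintf("no factor for sample: %s",
                        colnames(m)[which(is.na(idx))[1]]),
                "spikeshift_lookup_error")
    m <- sweep(m, 2, factors$nf[idx], `*`)
  } else if (normalization == "library_size") {
    m <- sweep(m, 2, colSums(signal$counts) / 1e6, `/`)
  }
  m
}

#' Strand-aware promoter windows around TSSs
#'
#' Extends single-base TSS records `upstream` bases against the direction of
#' transcription and `downstream` bases with it (bedtools-slop semantics),
#' clamped to the chromosome.  Defaults follow the generous promoter
#' convention (10 kb upstream, 1 kb downstream); the bivalent-promoter
#' variant uses (1 kb, 100 bp).
#'
#' @param tss an [intervals()] data frame of single-base stranded records.
#' @param upstream,downstream extension in bases.
#' @param genome a [genome_index()] for clamping.
#' @return an [intervals()] data frame of windows (name/strand carried over).
#' @export
promoter_windows <- function(tss, upstream = 10000, downstream = 1000,
                             genome) {
  bad <- setdiff(unique(tss$chrom), names(genome))
  assert_that(length(bad) == 0,
              sprintf("unknown chromosome: %s", bad[1]),
              "spikeshift_lookup_error")
  assert_that(all(tss$end - tss$start == 1),
              "TSS records must be single-base intervals")
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$start - downstream, tss$start - upstream)
  end <- ifelse(minus, tss$end + upstream, tss$end + downstream)
  lens <- unname(genome[tss$chrom])
  intervals(tss$chrom, pmax(start, 0), pmin(end, lens),
            name = tss$name, strand = tss$strand)
}

#' Baseline peaks at bivalent promoters
#'
#' Builds bivalent promoter windows (1 kb upstream, 100 bp downstream by
#' default) around the supplied TSSs and returns the subset of baseline
#' peaks overlapping at least one window, each peak reported once.
#'
#' @param bivalent_gene_tss [intervals()] of stranded single-base TSSs.
#' @param baseline_peaks [intervals()] of peaks (e.g. from
#'   [merge_and_intersect()]).
#' @param genome a [genome_index()].
#' @param upstream,downstream window extensions (bivalent defaults).
#' @return the overlapping subset of `baseline_peaks`, in input order.
#' @export
bivalent_peak_set <- function(bivalent_gene_tss, baseline_peaks, genome,
                              upstream = 1000, downstream = 100) {
  if (nrow(baseline_peaks) == 0 || nrow(bivalent_gene_tss) == 0) {
    return(baseline_peaks[integer(0), , drop = FALSE])
  }
  windows <- promoter_windows(bivalent_gene_tss, upstream, downstream, genome)
  hits <- GenomicRanges::findOverlaps(as_granges(baseline_peaks),
                                      as_granges(windows),
                                      ignore.strand = TRUE)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  baseline_peaks[keep, , drop = FALSE]
}

#' Classify repeat elements by spike-normalized signal ratio
#'
#' An element is `hyper` when `log2(high/ctrl) > log2_threshold` and its
#' high-condition signal exceeds `min_hyper`; `hypo` when
#' `log2(high/ctrl) < -log2_threshold` and the high-condition signal is
#' below `max_hypo`; otherwise `neither`.  Elements with zero control
#' signal cannot form a ratio; they are excluded and tallied in the
#' `n_excluded` attribute.
#'
#' @param high,ctrl aligned numeric vectors of replicate-averaged
#'   normalized counts (high condition, control).
#' @param elements optional element names/families.
#' @param min_hyper,max_hypo,log2_threshold classification thresholds
#'   (defaults 5, 3, 0.7).
#' @return data frame `element`, `high_signal`, `ctrl_signal`,
#'   `log2_ratio`, `class`; excluded-element count as attribute.
#' @export
classify_repeat_elements <- function(high, ctrl, elements = NULL,
                                     min_hyper = 5, max_hypo = 3,
                                     log2_threshold = 0.7) {
  assert_that(length(high) == length(ctrl),
              "element lists not aligned", "spikeshift_alignment_error")
  if (is.null(elements)) elements <- sprintf("element_%04d", seq_along(high))
  ok <- ctrl > 0
  lr <- log2(high[ok] / ctrl[ok])
  cls <- rep("neither", sum(ok))
  cls[lr > log2_threshold & high[ok] > min_hyper] <- "hyper"
  cls[lr < -log2_threshold & high[ok] < max_hypo] <- "hypo"
  out <- data.frame(element = elements[ok], high_signal = high[ok],
                    ctrl_signal = ctrl[ok], log2_ratio = lr, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  ss_log("classify_repeat_elements: %d hyper, %d hypo, %d neither, %d excluded",
         sum(cls == "hyper"), sum(cls == "hypo"), sum(cls == "neither"),
         sum(!ok))
  out
}

#' Signal matrix over regions (heatmap/profile input)
#'
#' Builds a regions x positions matrix of binned signal, either anchored at
#' a reference point (region start, center or end; `+/-flank` bases at bin
#' resolution) or with the region body rescaled to `body_bins` positions
#' plus fixed-width flanks.  Minus-strand regions are reversed so that all
#' rows read 5' to 3'.  Positions falling off a chromosome are `NA`
#' (missing) unless `missing_as_zero` is set.  The mean profile is the
#' column mean over non-missing entries, and `row_order` sorts rows by
#' descending row mean (the heatmap convention).
#'
#' @param signal a [bin_matrix()] of uniform-width bins.
#' @param regions an [intervals()] data frame.
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param flank flank size in bases.
#' @param body_bins body positions for `"scale_regions"`.
#' @param anchor reference point for `"reference_point"` mode.
#' @param sample sample column to use; default averages all columns.
#' @param missing_as_zero treat off-chromosome positions as 0.
#' @return list with `matrix`, `profile`, `positions`, `row_order`.
#' @export
aggregate_signal_matrix <- function(signal, regions,
                                    mode = c("reference_point",
                                             "scale_regions"),
                                    flank = 5000, body_bins = 500,
                                    anchor = c("start", "center", "end"),
                                    sample = NULL, missing_as_zero = FALSE) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  assert_that(flank > 0, "flank must be positive")
  if (mode == "scale_regions") {
    assert_that(body_bins > 0, "body_bins must be positive")
  }
  vals <- if (is.null(sample)) rowMeans(signal$counts) else {
    assert_that(sample %in% colnames(signal$counts),
                sprintf("unknown sample: %s", sample),
                "spikeshift_lookup_error")
    signal$counts[, sample]
  }
  bw <- max(signal$bins$end - signal$bins$start)
  # genomic position -> bin value lookup, per chromosome
  chrom_levels <- unique(signal$bins$chrom)
  offsets <- c(0, cumsum(as.numeric(table(factor(signal$bins$chrom,
                                                 chrom_levels)))))
  names(offsets) <- c(chrom_levels, "_end")
  chrom_len <- tapply(signal$bins$end, factor(signal$bins$chrom,
                                              chrom_levels), max)
  lookup <- function(chrom, pos) {
    ok <- pos >= 0 & pos < chrom_len[[chrom]]
    out <- rep(NA_real_, length(pos))
    idx <- offsets[[chrom]] + floor(pos[ok] / bw) + 1
    out[ok] <- vals[idx]
    if (missing_as_zero) out[!ok] <- 0
    out
  }
  n_flank <- round(flank / bw)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    chrom <- regions$chrom[i]
    minus <- regions$strand[i] == "-"
    if (mode == "reference_point") {
      ref <- switch(anchor,
                    start = if (minus) regions$end[i] else regions$start[i],
                    end = if (minus) regions$start[i] else regions$end[i],
                    center = (regions$start[i] + regions$end[i]) / 2)
      pos <- ref + (seq(-n_flank, n_flank - 1) + 0.5) * bw
    } else {
      w <- regions$end[i] - regions$start[i]
      body <- regions$start[i] + (seq_len(body_bins) - 0.5) / body_bins * w
      up <- regions$start[i] + (seq(-n_flank, -1) + 0.5) * bw
      down <- regions$end[i] + (seq_len(n_flank) - 0.5) * bw
      pos <- c(up, body, down)
    }
    v <- lookup(chrom, pos)
    if (minus) rev(v) else v
  })
  m <- do.call(rbind, rows)
  if (mode == "reference_point") {
    colnames(m) <- sprintf("%d", as.integer((seq(-n_flank, n_flank - 1)
                                             + 0.5) * bw))
  }
  profile <- colMeans(m, na.rm = TRUE)
  row_means <- rowMeans(m, na.rm = TRUE)
  list(matrix = m, profile = profile,
       positions = seq_len(ncol(m)),
       row_order = order(row_means, decreasing = TRUE))
}
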