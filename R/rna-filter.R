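#' Filter low-expression genes
#'
#' Two modes matching the two study arms.  ES mode drops genes with a zero
#' count in any sample and genes whose counts-per-million do not exceed
#' `cpm_threshold` in at least one sample (`cpm_rule = "all"`: a gene
#' survives if any sample exceeds the threshold; `"any"` drops a gene as
#' soon as one sample is at or below it).  Embryo mode drops genes whose
#' total raw count across all samples is below `min_total`.  Spike-in rows
#' are never filtered.
#'
#' @param counts a `ss_count_matrix` (see [count_matrix()]).
#' @param mode `"es"` or `"embryo"`.
#' @param cpm_threshold CPM threshold (ES mode, default 3); CPM uses the
#'   full column totals of the table.
#' @param cpm_rule `"all"` (default) or `"any"`, see above.
#' @param min_total minimum total raw count (embryo mode, default 10).
#' @return the filtered `ss_count_matrix`.
#' @export
filter_low_expression <- function(counts, mode = c("es", "embryo"),
                                  cpm_threshold = 3, cpm_rule = c("all",
                                                                  "any"),
                                  min_total = 10) {
  mode <- match.arg(mode)
  cpm_rule <- match.arg(cpm_rule)
  m <- counts$counts
  gene <- !counts$is_spike
  if (mode == "es") {
    cpm <- sweep(m, 2, colSums(m) / 1e6, `/`)
    no_zero <- rowSums(m == 0) == 0
    pass_cpm <- if (cpm_rule == "all") {
      rowSums(cpm > cpm_threshold) > 0
    } else {
      rowSums(cpm <= cpm_threshold) == 0
    }
    keep <- !gene | (no_zero & pass_cpm)
  } else {
    keep <- !gene | rowSums(m) >= min_total
  }
  assert_that(any(keep & gene), "all genes filtered out",
              "spikeshift_degenerate_error")
  ss_log("filter_low_expression (%s): kept %d of %d genes (+%d spikes)",
         mode, sum(keep & gene), sum(gene), sum(!gene))
  count_matrix(m[keep, , drop = FALSE], spike_prefix = counts$spike_prefix)
}
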