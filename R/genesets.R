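#' Fisher-exact gene-set overlap enrichment
#'
#' For each annotation set, forms the 2x2 table of membership in the query
#' versus the annotation over the universe and computes the one-sided
#' (enrichment) hypergeometric tail p-value, the sample odds ratio from the
#' table, and BH-adjusted p-values across annotations.  Annotations are
#' intersected with the universe before testing; a set disjoint from the
#' universe yields a row flagged degenerate.
#'
#' @param query character vector of gene identifiers (must lie within the
#'   universe).
#' @param annotations named list of character vectors.
#' @param universe character vector: the gene universe.
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @return data frame: `set`, `overlap` (k), `query_size` (n), `set_size`
#'   (K), `universe_size` (N), `odds_ratio`, `p`, `padj`, `degenerate`,
#'   sorted by `padj`.
#' @export
fisher_overlap <- function(query, annotations, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  query <- unique(query)
  assert_that(all(query %in% universe), "query must lie within the universe")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(annotations), function(nm) {
    ann <- intersect(unique(annotations[[nm]]), universe)
    K <- length(ann)
    k <- length(intersect(query, ann))
    if (K == 0) {
      return(data.frame(set = nm, overlap = 0L, query_size = n,
                        set_size = 0L, universe_size = N,
                        odds_ratio = NA_real_, p = 1, degenerate = TRUE))
    }
    if (alternative == "greater") {
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      p <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2),
                              alternative = "two.sided")$p.value
    }
    or <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    if (!is.finite(or)) or <- Inf
    if (k == 0) or <- 0
    data.frame(set = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, odds_ratio = or, p = p,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out[order(out$padj, out$p), c("set", "overlap", "query_size", "set_size",
                                "universe_size", "odds_ratio", "p", "padj",
                                "degenerate")]
}

#' Percentage of one gene set contained in another
#'
#' `100 * |a intersect b| / |a|`.  `reported` rounds to the nearest whole
#' percent, the convention used when quoting overlap counts.
#'
#' @param a,b character vectors of gene identifiers; `a` must be non-empty.
#' @return list with `percent` (exact) and `reported` (rounded integer).
#' @export
#' @examples
#' percent_overlap(letters[1:4], letters[1:3])
percent_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  assert_that(length(a) > 0, "empty query set",
              "spikeshift_degenerate_error")
  pct <- 100 * length(intersect(a, b)) / length(a)
  list(percent = pct, reported = as.integer(round(pct)))
}

#' Seeded uniform random gene subset
#'
#' Uniform sample without replacement, reproducible from `seed` and leaving
#' the caller's RNG state untouched.
#'
#' @param universe character vector to sample from.
#' @param n subset size (`n <= |universe|`).
#' @param seed integer seed (mandatory: random baselines must be loggable).
#' @return character vector of length `n`.
#' @export
random_subset <- function(universe, n, seed) {
  assert_that(n <= length(universe), "n exceeds universe size")
  with_seed(seed, sample(universe, n))
}

#' Fold-change shift of a target gene set versus background
#'
#' Boxplot-convention summaries (hinges = quartiles, whiskers +/- 1.5 IQR)
#' of per-gene log2 fold-changes for the target and background sets, a
#' one-way ANOVA across the groups and pairwise two-sided Wilcoxon rank-sum
#' tests.
#'
#' @param fc named numeric vector of per-gene log2 fold-changes.
#' @param sets named list of character vectors (e.g. target and a random
#'   subset); each must intersect the fold-change genes.
#' @return list with `summaries` (one row per set), `anova_p`,
#'   `pairwise_p` (matrix of rank-sum p-values), `values` (per-set vectors).
#' @export
geneset_shift <- function(fc, sets) {
  assert_that(!is.null(names(fc)), "fc must be a named vector")
  values <- lapply(sets, function(s) fc[names(fc) %in% s])
  sizes <- lengths(values)
  assert_that(all(sizes > 0),
              sprintf("gene set '%s' has no genes with fold-changes",
                      names(sets)[which(sizes == 0)[1]]),
              "spikeshift_degenerate_error")
  summaries <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(set = nm, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
  }))
  grp <- factor(rep(names(values), lengths(values)), levels = names(values))
  all_v <- unlist(values, use.names = FALSE)
  anova_p <- if (nlevels(grp) >= 2) {
    summary(aov(all_v ~ grp))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  k <- length(values)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(values), names(values)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      pw[i, j] <- pw[j, i] <- suppressWarnings(
        wilcox.test(values[[i]], values[[j]], exact = FALSE)$p.value)
    }
  }
  list(summaries = summaries, anova_p = anova_p, pairwise_p = pw,
       values = values)
}
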