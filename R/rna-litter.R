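#' Two-group negative-binomial Wald test on raw counts
#'
#' A self-contained NB test for count matrices: median-of-ratios size
#' factors, per-gene method-of-moments dispersion estimates shrunk (on the
#' log scale) toward a fitted mean-dispersion trend, and a Wald test on the
#' log fold-change with a delta-method standard error
#' `var(log mu_k) ~ (1/mu_k + disp) / n_k`.
#'
#' @param counts genes x samples matrix of raw counts.
#' @param groups two-level factor; contrast is level 2 minus level 1.
#' @param prior_weight weight of the trend in the log-scale dispersion
#'   shrinkage, relative to the per-gene residual degrees of freedom.
#' @param pseudo pseudocount added to normalized group means before the
#'   ratio.
#' @return a data frame `gene`, `base_mean`, `log2fc`, `stat`, `p`, `padj`.
#' @export
nb_wald_test <- function(counts, groups, prior_weight = 4, pseudo = 0.5) {
  groups <- factor(groups)
  assert_that(nlevels(groups) == 2, "groups must have exactly two levels")
  assert_that(all(table(groups) >= 2), "need >= 2 samples per group")
  sf <- size_factors(counts)
  q <- t(t(counts) / sf)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(q[, g1, drop = FALSE])
  mu2 <- rowMeans(q[, g2, drop = FALSE])
  mu <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  # method-of-moments dispersion from pooled within-group variance
  v_within <- (rowSums((q[, g1, drop = FALSE] - mu1)^2) +
                 rowSums((q[, g2, drop = FALSE] - mu2)^2)) / (n1 + n2 - 2)
  disp_raw <- pmax((v_within - mu) / mu^2, 1e-8)
  disp <- shrink_dispersion(disp_raw, mu, df = n1 + n2 - 2,
                            prior_weight = prior_weight)
  lfc <- log2((mu2 + pseudo) / (mu1 + pseudo))
  se2 <- (1 / (mu1 + pseudo) + disp) / n1 +
    (1 / (mu2 + pseudo) + disp) / n2
  stat <- (log(mu2 + pseudo) - log(mu1 + pseudo)) / sqrt(se2)
  p <- 2 * pnorm(-abs(stat))
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(counts), base_mean = mu, log2fc = lfc,
             stat = stat, p = p, padj = padj, row.names = NULL,
             stringsAsFactors = FALSE)
}

# DESeq-style median-of-ratios size factors, falling back to relative
# column totals when too few genes are expressed everywhere.
size_factors <- function(counts) {
  logs <- log(counts)
  ok <- rowSums(is.finite(logs)) == ncol(counts)
  if (sum(ok) >= 10) {
    geo <- rowMeans(logs[ok, , drop = FALSE])
    sf <- apply(logs[ok, , drop = FALSE], 2,
                function(col) exp(median(col - geo)))
  } else {
    sf <- colSums(counts)
    sf <- sf / geometric_mean(sf)
  }
  sf
}

# Log-scale shrinkage of gene-wise dispersions toward a fitted 1/mu trend.
shrink_dispersion <- function(disp_raw, mu, df, prior_weight) {
  ok <- mu > 0 & disp_raw > 1e-8
  trend <- if (sum(ok) >= 10) {
    fit <- stats::lm(disp_raw[ok] ~ I(1 / mu[ok]))
    co <- pmax(stats::coef(fit), 0)
    pmax(co[1] + co[2] / pmax(mu, 1e-8), 1e-8)
  } else {
    rep(max(median(disp_raw), 1e-8), length(disp_raw))
  }
  exp((df * log(disp_raw) + prior_weight * log(trend)) / (df + prior_weight))
}

#' Litter-matched differential expression overlap
#'
#' Calls differential expression between mutants and controls separately
#' within each litter with [nb_wald_test()], applies the adjusted-p cutoff,
#' and intersects the per-litter gene lists: the final up set contains
#' genes significant with positive fold-change in every litter (down
#' analogous); genes significant but direction-discordant across litters
#' are excluded.
#'
#' @param counts a `ss_count_matrix` of raw counts (spike rows ignored).
#' @param litter_labels per-sample litter identifiers (>= 2 litters).
#' @param condition_labels per-sample two-level factor (control first
#'   level, mutant second); every litter needs both levels.
#' @param padj_cutoff adjusted-p threshold (default 0.1).
#' @return list with `up`, `down` (character vectors) and `per_litter`
#'   (named list of per-litter DE tables).
#' @export
litter_matched_de <- function(counts, litter_labels, condition_labels,
                              padj_cutoff = 0.1) {
  m <- counts$counts[!counts$is_spike, , drop = FALSE]
  litter <- factor(litter_labels)
  cond <- factor(condition_labels)
  assert_that(nlevels(litter) >= 2, "need at least 2 litters")
  assert_that(nlevels(cond) == 2, "condition must have two levels")
  tables <- list()
  up_sets <- list(); down_sets <- list()
  for (l in levels(litter)) {
    cols <- litter == l
    assert_that(all(table(droplevels(cond[cols])) >= 2) &&
                  nlevels(droplevels(cond[cols])) == 2,
                sprintf("litter '%s' is missing a condition group", l))
    tab <- nb_wald_test(m[, cols, drop = FALSE], droplevels(cond[cols]))
    tables[[l]] <- tab
    sig <- tab$padj < padj_cutoff
    up_sets[[l]] <- tab$gene[sig & tab$log2fc > 0]
    down_sets[[l]] <- tab$gene[sig & tab$log2fc < 0]
  }
  up <- Reduce(intersect, up_sets)
  down <- Reduce(intersect, down_sets)
  ss_log("litter_matched_de: %d litters, %d up / %d down after overlap",
         nlevels(litter), length(up), length(down))
  list(up = up, down = down, per_litter = tables)
}
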