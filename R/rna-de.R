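#' Moderated-t differential expression on log expression
#'
#' Per-gene two-group linear contrast (second factor level minus first) on
#' (typically CNN) log2 expression, with residual variances shrunk toward a
#' common prior by empirical Bayes: the prior degrees of freedom `d0` and
#' prior variance `s0^2` are fitted by moment matching of the observed
#' log-variance distribution (scaled-F model), the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t carries `d0 + d`
#' degrees of freedom.  P-values are BH-adjusted and genes are labelled
#' `up`/`down`/`ns` by the stated thresholds.
#'
#' @param logexpr genes x samples matrix of log2 expression.
#' @param groups two-level factor over the samples; the contrast is
#'   `levels(groups)[2] - levels(groups)[1]`.
#' @param weights optional genes x samples matrix of per-observation
#'   precision weights (e.g. from a fitted mean-variance trend).
#' @param prior_df override the fitted prior degrees of freedom (0 recovers
#'   the ordinary equal-variance two-sample t-test).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.7).
#' @return a `DETable` data frame: `gene`, `log2fc`, `t`, `df`, `p`,
#'   `padj`, `status`; fitted `d0`, `s02` as attributes.
#' @export
moderated_de <- function(logexpr, groups, weights = NULL, prior_df = NULL,
                         alpha = 0.05, lfc_threshold = 0.7) {
  groups <- factor(groups)
  assert_that(nlevels(groups) == 2, "groups must have exactly two levels")
  assert_that(all(table(groups) >= 2), "need >= 2 samples per group")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  d <- n1 + n2 - 2
  assert_that(d > 0, "zero residual degrees of freedom",
              "spikeshift_degenerate_error")
  if (is.null(weights)) {
    m1 <- rowMeans(logexpr[, g1, drop = FALSE])
    m2 <- rowMeans(logexpr[, g2, drop = FALSE])
    ssr <- rowSums((logexpr[, g1, drop = FALSE] - m1)^2) +
      rowSums((logexpr[, g2, drop = FALSE] - m2)^2)
    stdev_unscaled <- sqrt(1 / n1 + 1 / n2)
    s2 <- ssr / d
  } else {
    assert_that(all(dim(weights) == dim(logexpr)),
                "weights must match logexpr dimensions")
    w1 <- weights[, g1, drop = FALSE]; w2 <- weights[, g2, drop = FALSE]
    m1 <- rowSums(w1 * logexpr[, g1, drop = FALSE]) / rowSums(w1)
    m2 <- rowSums(w2 * logexpr[, g2, drop = FALSE]) / rowSums(w2)
    ssr <- rowSums(w1 * (logexpr[, g1, drop = FALSE] - m1)^2) +
      rowSums(w2 * (logexpr[, g2, drop = FALSE] - m2)^2)
    stdev_unscaled <- sqrt(1 / rowSums(w1) + 1 / rowSums(w2))
    s2 <- ssr / d
  }
  beta <- m2 - m1
  if (is.null(prior_df)) {
    fit <- fit_f_dist(s2, d)
    d0 <- fit$df_prior; s02 <- fit$var_prior
  } else {
    d0 <- prior_df
    s02 <- if (prior_df > 0) fit_f_dist(s2, d)$var_prior else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tstat <- beta / (sqrt(s2_post) * stdev_unscaled)
  # cap at the pooled residual df: the prior cannot be more informative
  # than the whole data set it was fitted on
  df_total <- min(d0 + d, d * nrow(logexpr))
  p <- 2 * pt(-abs(tstat), df = df_total)
  padj <- p.adjust(p, method = "BH")
  status <- rep("ns", length(p))
  status[padj < alpha & beta > lfc_threshold] <- "up"
  status[padj < alpha & beta < -lfc_threshold] <- "down"
  out <- data.frame(gene = rownames(logexpr), log2fc = beta, t = tstat,
                    df = df_total, p = p, padj = padj, status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  ss_log("moderated_de: %d genes, d0=%.2f, %d up / %d down at padj<%g,|lfc|>%g",
         nrow(out), d0, sum(status == "up"), sum(status == "down"),
         alpha, lfc_threshold)
  out
}

# Moment-matching fit of a scaled-F distribution to sample variances:
# log s^2 = log s0^2 + log F(d, d0) up to additive digamma constants.
fit_f_dist <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  z <- z[is.finite(z) & s2 > 0]
  if (length(z) < 2) return(list(df_prior = Inf, var_prior = mean(s2)))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # variances are consistent with a point-mass prior: infinite prior df,
    # prior variance estimated by the plain mean
    d0 <- Inf
    s02 <- mean(s2[is.finite(s2)])
  }
  list(df_prior = d0, var_prior = s02)
}

# Newton solve of trigamma(y) = x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Global expression shift between two sample groups
#'
#' Per-gene log2 fold-changes (mean treated minus mean control on the CNN
#' log scale) with boxplot summaries (hinges = quartiles, whiskers at
#' +/- 1.5 IQR) and a two-sided Wilcoxon rank-sum test of the fold-change
#' list against a zero-centered null fold-change list.  By default the null
#' is built by contrasting the two halves of the control group against each
#' other; an explicit `null_fc` vector can be supplied instead.
#'
#' @param logexpr genes x samples log2 expression matrix.
#' @param treated,control character vectors of sample names (disjoint).
#' @param null_fc optional explicit null fold-change vector.
#' @return list with `fc` (named per-gene log2FC), `summary` (median,
#'   quartiles, whiskers), `p` (rank-sum), `null_fc`.
#' @export
global_shift <- function(logexpr, treated, control, null_fc = NULL) {
  assert_that(length(treated) > 0 && length(control) > 0,
              "empty sample group")
  assert_that(length(intersect(treated, control)) == 0,
              "treated and control groups overlap")
  assert_that(all(c(treated, control) %in% colnames(logexpr)),
              "unknown sample name", "spikeshift_lookup_error")
  fc <- rowMeans(logexpr[, treated, drop = FALSE]) -
    rowMeans(logexpr[, control, drop = FALSE])
  if (is.null(null_fc)) {
    if (length(control) >= 2) {
      half <- seq_len(floor(length(control) / 2))
      null_fc <- rowMeans(logexpr[, control[half], drop = FALSE]) -
        rowMeans(logexpr[, control[-half], drop = FALSE])
    } else {
      null_fc <- rep(0, length(fc))
    }
  }
  q <- quantile(fc, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  summary <- c(median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
  p <- suppressWarnings(wilcox.test(fc, null_fc,
                                    alternative = "two.sided",
                                    exact = FALSE)$p.value)
  # fully tied comparison (e.g. both lists constant): no evidence of a shift
  if (is.na(p)) p <- 1
  ss_log("global_shift: median log2FC %.3f (%d genes), rank-sum p %.3g",
         q[2], length(fc), p)
  list(fc = fc, summary = summary, p = p, null_fc = null_fc)
}

#' Precision weights from a fitted mean-variance trend
#'
#' Computes per-observation precision weights for [moderated_de()] by the
#' voom procedure: per-gene residual standard deviations from the group
#' model are square-root-transformed and regressed (lowess) on average log2
#' count; each observation's fitted count is then interpolated on the trend
#' and the weight is the inverse fourth power of the predicted root-sd.
#' Weights matter mainly for low-count genes, whose log-scale variance sits
#' above a shared prior and would otherwise be over-shrunk.
#'
#' @param counts a `ss_count_matrix` (only gene rows are used).
#' @param factors a `cnn_factors` data frame (effective library sizes).
#' @param groups two-level factor over the samples.
#' @param span lowess span (default 0.5).
#' @param prior prior count of the log transformation (default 0.5).
#' @return genes x samples matrix of precision weights.
#' @export
voom_weights <- function(counts, factors, groups, span = 0.5, prior = 0.5) {
  groups <- factor(groups)
  y <- cnn_log_expression(counts, factors, prior = prior)
  idx <- match(colnames(y), factors$sample)
  lib <- factors$effective_size[idx]
  g1 <- groups == levels(groups)[1]
  fitted <- y
  fitted[, g1] <- rowMeans(y[, g1, drop = FALSE])
  fitted[, !g1] <- rowMeans(y[, !g1, drop = FALSE])
  df <- ncol(y) - 2
  sigma <- sqrt(rowSums((y - fitted)^2) / df)
  amean <- rowMeans(y)
  sx <- amean + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  # low discrete counts produce tied x values; lowess collapses them
  lo <- suppressWarnings(lowess(sx[ok], sy[ok], f = span))
  lofun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_count <- log2(2^fitted * 1e-6 * (rep(lib, each = nrow(y)) + 1))
  w <- 1 / lofun(fitted_count)^4
  matrix(w, nrow(y), ncol(y), dimnames = dimnames(y))
}
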