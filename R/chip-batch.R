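#' Location/scale empirical-Bayes batch adjustment
#'
#' Removes additive and multiplicative batch effects from a log-scale
#' feature x sample matrix.  Each feature is standardized to its pooled
#' (batch-size weighted) mean and variance; per-batch location and scale
#' parameters are then estimated and, by default, shrunk toward their
#' across-feature means with parametric empirical-Bayes priors (normal for
#' locations, inverse-gamma for scales) before being regressed out.  With
#' `shrink = FALSE` the raw per-batch estimates are used, which removes
#' per-feature batch means exactly.
#'
#' @param x a [bin_matrix()] of log-scale values, or a plain
#'   feature x sample matrix.
#' @param batch_labels character/factor of length `ncol`, one batch label
#'   per sample; every batch needs at least 2 samples.
#' @param shrink use empirical-Bayes shrinkage of the batch parameters
#'   (default `TRUE`).
#' @param tol relative-change convergence tolerance of the EB iterations.
#' @return the adjusted object, same class as `x`.  A single batch returns
#'   `x` unchanged.
#' @export
batch_adjust <- function(x, batch_labels, shrink = TRUE, tol = 1e-4) {
  is_bm <- inherits(x, "ss_bin_matrix")
  m <- if (is_bm) x$counts else as.matrix(x)
  batch <- factor(batch_labels)
  assert_that(length(batch) == ncol(m),
              "one batch label per sample required")
  sizes <- table(batch)
  assert_that(all(sizes >= 2),
              sprintf("batch '%s' has fewer than 2 samples",
                      names(sizes)[which(sizes < 2)[1]]),
              "spikeshift_degenerate_error")
  if (nlevels(batch) == 1) return(x)

  n <- ncol(m)
  levels_b <- levels(batch)
  # per-feature, per-batch means; pooled mean and variance
  batch_means <- vapply(levels_b, function(b)
    rowMeans(m[, batch == b, drop = FALSE]), numeric(nrow(m)))
  grand_mean <- batch_means %*% (as.numeric(sizes[levels_b]) / n)
  resid <- m - batch_means[, as.integer(batch)]
  var_pooled <- rowSums(resid^2) / n
  var_pooled[var_pooled == 0] <- .Machine$double.eps
  z <- (m - as.numeric(grand_mean)) / sqrt(var_pooled)

  z_adj <- z
  for (b in levels_b) {
    cols <- which(batch == b)
    nb <- length(cols)
    zb <- z[, cols, drop = FALSE]
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1, var)
    delta_hat[delta_hat == 0] <- .Machine$double.eps
    if (shrink) {
      gamma_bar <- mean(gamma_hat); t2 <- var(gamma_hat)
      dm <- mean(delta_hat); ds2 <- var(delta_hat)
      a_prior <- (2 * ds2 + dm^2) / ds2
      b_prior <- (dm * ds2 + dm^3) / ds2
      g_old <- gamma_hat; d_old <- delta_hat
      repeat {
        g_new <- (t2 * nb * gamma_hat + d_old * gamma_bar) /
          (t2 * nb + d_old)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / d_old, na.rm = TRUE)
        g_old <- g_new; d_old <- d_new
        if (change < tol) break
      }
      gamma_star <- g_old; delta_star <- d_old
    } else {
      gamma_star <- gamma_hat; delta_star <- delta_hat
    }
    z_adj[, cols] <- (zb - gamma_star) / sqrt(delta_star)
  }
  out <- z_adj * sqrt(var_pooled) + as.numeric(grand_mean)
  ss_log("batch_adjust: %d features x %d samples, %d batches, shrink=%s",
         nrow(m), n, nlevels(batch), shrink)
  if (is_bm) bin_matrix(x$bins, out, x$scale_applied) else out
}

#' PCA embedding of samples over genomic bins
#'
#' Principal components of the sample x bin matrix (features centered, not
#' scaled).  The sign of each component is fixed by convention: the loading
#' with the largest magnitude is made positive, so repeated runs are
#' bit-identical.
#'
#' @param x a [bin_matrix()] or a feature x sample matrix.
#' @param n_components number of components to return.
#' @return list with `coords` (samples x components), `var_explained`
#'   (fractions, sum <= 1) and `loadings`.
#' @export
pca_embed <- function(x, n_components = 2) {
  m <- if (inherits(x, "ss_bin_matrix")) x$counts else as.matrix(x)
  assert_that(ncol(m) >= 2, "need at least 2 samples")
  assert_that(ncol(m) >= n_components,
              "fewer samples than requested components")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(load[which.max(abs(load[, j])), j])
    if (flip < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  rownames(scores) <- colnames(m)
  list(coords = scores, var_explained = ve, loadings = load)
}
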