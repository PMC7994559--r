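test_that("ES filter drops zero-containing and uniformly low-CPM genes", {
  m <- rbind(zeroed = c(0, 50, 50),
             low = c(29, 25, 10),
             ok = c(29, 35, 10),
             `ERCC-1` = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  # column sums 10^4 scale so CPM = count * 100 -> threshold 3 CPM = 30
  m <- rbind(m, filler = c(9941, 9889, 9929))
  cm <- count_matrix(m, spike_prefix = "ERCC-")
  out <- filter_low_expression(cm, mode = "es", cpm_threshold = 3000)
  kept <- rownames(out$counts)
  expect_false("zeroed" %in% kept)   # zero in one sample
  expect_false("low" %in% kept)      # CPM <= threshold in all samples
  expect_true("ok" %in% kept)        # one sample above threshold
  expect_true("ERCC-1" %in% kept)    # spikes never filtered
})

test_that("embryo filter applies the 'fewer than 10 raw counts' boundary", {
  m <- rbind(nine = c(3, 3, 3), ten = c(4, 3, 3), big = c(100, 100, 100))
  colnames(m) <- paste0("s", 1:3)
  cm <- count_matrix(m)
  out <- filter_low_expression(cm, mode = "embryo", min_total = 10)
  expect_equal(rownames(out$counts), c("ten", "big"))
  expect_error(filter_low_expression(count_matrix(m[1, , drop = FALSE]),
                                     mode = "embryo", min_total = 1000),
               class = "spikeshift_degenerate_error")
})

test_that("identical samples get unit factors; permutation permutes them", {
  m <- rbind(matrix(rep(c(50, 200, 1000), 4), 3, 4),
             matrix(rep(c(5000, 800), 4), 2, 4))
  rownames(m) <- c(paste0("ERCC-", 1:3), "geneA", "geneB")
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, spike_prefix = "ERCC-")
  f <- cnn_norm_factors(cm)
  expect_equal(f$nf, rep(1, 4))
  expect_equal(f$lib_size, rep(5800, 4), ignore_attr = TRUE)
  set.seed(91)
  m2 <- m + matrix(rpois(20, 20), 5, 4)
  cm2 <- count_matrix(m2, spike_prefix = "ERCC-")
  f2 <- cnn_norm_factors(cm2)
  perm <- c(3, 1, 4, 2)
  cm2p <- count_matrix(m2[, perm], spike_prefix = "ERCC-")
  f2p <- cnn_norm_factors(cm2p)
  expect_equal(f2p$nf, f2$nf[perm])
})

test_that("factors equal the brute-force trimmed-weighted-mean oracle", {
  set.seed(55)
  for (i in 1:20) {
    n_s <- sample(3:6, 1)
    # jitter breaks ties so the order-based oracle trim is unambiguous
    spikes <- matrix(rpois(10 * n_s, lambda = sample(50:500, 10,
                                                     replace = TRUE)) +
                       runif(10 * n_s) * 0.01,
                     10, n_s)
    genes <- matrix(rpois(30 * n_s, 300), 30, n_s)
    m <- rbind(spikes, genes)
    rownames(m) <- c(paste0("ERCC-", 1:10), paste0("g", 1:30))
    colnames(m) <- paste0("s", seq_len(n_s))
    if (any(colSums(spikes) == 0)) next
    cm <- count_matrix(m, spike_prefix = "ERCC-")
    got <- cnn_norm_factors(cm)$nf
    want <- oracle_cnn_factors(spikes, colSums(genes))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("factors agree with the reference edgeR TMM implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulate_rna_experiment(rna_sim_params(n_genes = 500,
                                                g_global = 2, depth = 2e5,
                                                seed = 33))
  f <- filter_low_expression(sim$counts)
  got <- cnn_norm_factors(f)
  spikes <- f$counts[f$is_spike, ]
  N <- colSums(f$counts[!f$is_spike, ])
  ref <- edgeR::calcNormFactors(spikes, lib.size = N, method = "TMM")
  expect_equal(got$nf, unname(ref), tolerance = 1e-12)
})

test_that("CNN log expression follows the stated transformation", {
  m <- rbind(g1 = c(0, 1000), g2 = c(1000, 2000), `ERCC-1` = c(10, 10))
  colnames(m) <- c("a", "b")
  cm <- count_matrix(m, spike_prefix = "ERCC-")
  fac <- data.frame(sample = c("a", "b"), effective_size = c(1e6, 1e6))
  le <- cnn_log_expression(cm, fac)
  expect_equal(le["g1", "a"], log2(0.5 / (1e6 + 1) * 1e6))
  expect_false("ERCC-1" %in% rownames(le))
  # doubling a large count raises the value by about 1
  expect_equal(le["g2", "b"] - le["g2", "a"], 1, tolerance = 1e-3)
  # monotone in the count
  expect_true(le["g2", "a"] > le["g1", "a"])
})

test_that("CNN log expression matches the reference voom transformation", {
  skip_if_not_installed("limma")
  sim <- simulate_rna_experiment(rna_sim_params(n_genes = 300, depth = 1e5,
                                                seed = 44))
  f <- filter_low_expression(sim$counts)
  fac <- cnn_norm_factors(f)
  le <- cnn_log_expression(f, fac)
  gr <- factor(rep(c("a", "b"), each = 3))
  v <- suppressWarnings(limma::voom(f$counts[!f$is_spike, ],
                                    stats::model.matrix(~gr),
                                    lib.size = fac$effective_size))
  expect_equal(le, v$E, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("CNN recovers a global doubling that naive scaling hides", {
  sim <- simulate_rna_experiment(rna_sim_params(n_genes = 2000,
                                                g_global = 2, depth = 1e6,
                                                n_replicates = 3,
                                                seed = 101))
  f <- filter_low_expression(sim$counts)
  fac <- cnn_norm_factors(f)
  le <- cnn_log_expression(f, fac)
  treated <- sim$samples$sample[sim$samples$condition == "treated"]
  control <- sim$samples$sample[sim$samples$condition == "control"]
  cnn_med <- global_shift(le, treated, control)$summary[["median"]]
  naive_fac <- data.frame(sample = fac$sample,
                          effective_size = fac$lib_size)
  naive_med <- global_shift(cnn_log_expression(f, naive_fac),
                            treated, control)$summary[["median"]]
  expect_true(cnn_med >= 0.9 && cnn_med <= 1.1)
  expect_true(naive_med >= -0.1 && naive_med <= 0.1)
})
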