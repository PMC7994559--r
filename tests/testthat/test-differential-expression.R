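test_that("with zero prior df the moderated t is the ordinary t-test", {
  set.seed(61)
  y <- matrix(rnorm(50 * 6, 8), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  gr <- factor(rep(c("control", "treated"), each = 3),
               levels = c("control", "treated"))
  de <- moderated_de(y, gr, prior_df = 0)
  ref <- apply(y, 1, function(v) {
    tt <- t.test(v[4:6], v[1:3], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(de$t, unname(ref[1, ]), tolerance = 1e-10)
  expect_equal(de$p, unname(ref[2, ]), tolerance = 1e-10)
})

test_that("moderated statistics agree with the reference limma fit", {
  skip_if_not_installed("limma")
  set.seed(62)
  y <- matrix(rnorm(400 * 6, 8, 0.6), 400, 6,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
  gr <- factor(rep(c("control", "treated"), each = 3),
               levels = c("control", "treated"))
  de <- moderated_de(y, gr)
  fit <- limma::eBayes(limma::lmFit(y, stats::model.matrix(~gr)))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("precision weights match the reference voom weights", {
  skip_if_not_installed("limma")
  sim <- simulate_rna_experiment(rna_sim_params(n_genes = 500, depth = 2e5,
                                                seed = 63))
  f <- filter_low_expression(sim$counts)
  fac <- cnn_norm_factors(f)
  gr <- factor(rep(c("control", "treated"), each = 3),
               levels = c("control", "treated"))
  w <- voom_weights(f, fac, gr)
  v <- suppressWarnings(limma::voom(f$counts[!f$is_spike, ],
                                    stats::model.matrix(~gr),
                                    lib.size = fac$effective_size))
  expect_equal(w, v$weights, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("p-values are calibrated under the null simulation", {
  fractions <- vapply(1:20, function(s) {
    sim <- simulate_rna_experiment(rna_sim_params(g_global = 1,
                                                  seed = 1500 + s))
    f <- filter_low_expression(sim$counts)
    le <- cnn_log_expression(f, cnn_norm_factors(f))
    gr <- factor(ifelse(grepl("^treated", colnames(le)),
                        "treated", "control"),
                 levels = c("control", "treated"))
    mean(moderated_de(le, gr)$p < 0.05)
  }, numeric(1))
  expect_gte(mean(fractions), 0.03)
  expect_lte(mean(fractions), 0.07)
})

test_that("with mean-variance weights the combined threshold stays clean", {
  n_sig <- vapply(1:20, function(s) {
    sim <- simulate_rna_experiment(rna_sim_params(g_global = 1,
                                                  seed = 1500 + s))
    f <- filter_low_expression(sim$counts)
    fac <- cnn_norm_factors(f)
    le <- cnn_log_expression(f, fac)
    gr <- factor(ifelse(grepl("^treated", colnames(le)),
                        "treated", "control"),
                 levels = c("control", "treated"))
    de <- moderated_de(le, gr, weights = voom_weights(f, fac, gr))
    sum(de$status != "ns")
  }, numeric(1))
  expect_gte(mean(n_sig == 0), 0.95)
})

test_that("a strongly induced gene ranks first by adjusted p", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_rna_experiment(
      rna_sim_params(g_global = 1, de_spec = data.frame(gene = 1,
                                                        log2fc = 2),
                     seed = 2500 + s))
    f <- filter_low_expression(sim$counts)
    le <- cnn_log_expression(f, cnn_norm_factors(f))
    gr <- factor(ifelse(grepl("^treated", colnames(le)),
                        "treated", "control"),
                 levels = c("control", "treated"))
    de <- moderated_de(le, gr)
    de$gene[order(de$padj, de$p)][1] == "gene00001"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment is monotone and bounded below by p", {
  set.seed(64)
  y <- matrix(rnorm(200 * 4, 5), 200, 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  de <- moderated_de(y, factor(rep(c("a", "b"), each = 2)))
  expect_true(all(de$padj >= de$p))
  ord <- order(de$p)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
})

test_that("global_shift handles identity and recovers a global halving", {
  set.seed(65)
  y <- matrix(rnorm(100 * 4, 5), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  expect_error(global_shift(y, c("s1", "s2"), c("s2", "s3")), "overlap")
  # identical construction: both groups share the column values
  y2 <- cbind(y, y)
  colnames(y2) <- paste0("t", 1:8)
  gs <- global_shift(y2, paste0("t", 1:4), paste0("t", 5:8))
  expect_true(all(gs$fc == 0))
  expect_equal(gs$summary[["median"]], 0)
  # identical (non-degenerate) fold-change lists give rank-sum p = 1
  v <- rnorm(50)
  expect_equal(suppressWarnings(
    wilcox.test(v, v, exact = FALSE)$p.value), 1)
  sim <- simulate_rna_experiment(rna_sim_params(n_genes = 2000,
                                                g_global = 0.5,
                                                depth = 1e6, seed = 66))
  f <- filter_low_expression(sim$counts)
  le <- cnn_log_expression(f, cnn_norm_factors(f))
  treated <- sim$samples$sample[sim$samples$condition == "treated"]
  control <- sim$samples$sample[sim$samples$condition == "control"]
  gs2 <- global_shift(le, treated, control)
  expect_true(gs2$summary[["median"]] >= -1.1 &&
                gs2$summary[["median"]] <= -0.9)
  expect_lt(gs2$p, 1e-10)
})
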