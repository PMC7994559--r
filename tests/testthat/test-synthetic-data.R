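test_that("ChIP simulation conserves depth and is seed-reproducible", {
  p <- chip_sim_params(n_bins = 200, depth = 50000, n_replicates = 2,
                       r_global = 0.5, seed = 11)
  sim1 <- simulate_chip_experiment(p)
  sim2 <- simulate_chip_experiment(p)
  expect_identical(sim1$ip_bins$counts, sim2$ip_bins$counts)
  expect_identical(sim1$species_counts, sim2$species_counts)
  totals <- sim1$species_counts$target_reads + sim1$species_counts$spike_reads
  expect_true(all(totals == p$depth))
  # bin counts sum to the sample's target reads
  expect_equal(unname(colSums(sim1$ip_bins$counts)),
               sim1$species_counts$target_reads[
                 sim1$species_counts$role == "IP"])
})

test_that("ChIP target:spike split matches the closed-form expectation", {
  # r_global 0.5, spike fraction 0.1: treated target share = 0.45/0.55
  p <- chip_sim_params(n_bins = 500, depth = 1e6, n_replicates = 3,
                       r_global = 0.5, spike_fraction = 0.1, seed = 5)
  sim <- simulate_chip_experiment(p)
  sc <- sim$species_counts
  ip <- sc[sc$role == "IP", ]
  expected_ratio <- c(control = 0.9 / 0.1,
                      treated = (0.5 * 0.9) / 0.1)
  for (cond in names(expected_ratio)) {
    rows <- ip[ip$condition == cond, ]
    realized <- rows$target_reads / rows$spike_reads
    p_spike <- 1 / (1 + expected_ratio[[cond]])
    se <- sqrt(p_spike * (1 - p_spike) / p$depth) / p_spike^2
    expect_true(all(abs(realized - expected_ratio[[cond]]) < 3 * se))
  }
})

test_that("no-effect ChIP simulation has identical expected splits", {
  p <- chip_sim_params(n_bins = 100, depth = 1e5, r_global = 1, seed = 2)
  expect <- chip_expectation(p)
  e <- expect$samples
  by_cond <- tapply(e$expected_target / e$expected_spike,
                    paste(e$condition, e$role), unique)
  expect_equal(by_cond[["control IP"]], by_cond[["treated IP"]])
})

test_that("Monte-Carlo bin means converge to the expectation oracle", {
  dom <- data.frame(start_bin = 10, n_bins = 5, multiplier = 4)
  p <- chip_sim_params(n_bins = 50, depth = 20000, n_replicates = 1,
                       domain_spec = dom, r_global = 2, seed = 1,
                       input_uniformity = TRUE)
  expect <- chip_expectation(p)
  sample1 <- expect$samples$sample[1]
  reps <- vapply(seq_len(200), function(i) {
    pi <- chip_sim_params(n_bins = 50, depth = 20000, n_replicates = 1,
                          domain_spec = dom, r_global = 2, seed = 1000 + i,
                          input_uniformity = TRUE)
    simulate_chip_experiment(pi)$ip_bins$counts[, sample1]
  }, numeric(p$n_bins))
  mc_mean <- rowMeans(reps)
  mu <- expect$expected_bins[, sample1]
  se <- sqrt(mu) / sqrt(200)  # Poisson-scale spread of the MC average
  z <- (mc_mean - mu) / se
  # ~99.7% of bins should sit within 3 s.e.; allow the binomial wiggle a
  # 50-bin sample carries and catch any systematic bias via the mean
  expect_gte(mean(abs(z) <= 3), 0.94)
  expect_true(all(abs(z) <= 4.5))
  expect_lt(abs(mean(z)), 0.5)
})

test_that("chip domains raise an error when they exceed the genome", {
  expect_error(chip_sim_params(n_bins = 20,
                               domain_spec = data.frame(start_bin = 18,
                                                        n_bins = 5,
                                                        multiplier = 2)),
               "exceeds")
  expect_error(chip_sim_params(spike_fraction = 1.2), "spike_fraction")
})

test_that("RNA simulation is reproducible, depth-exact and spike-invariant", {
  p <- rna_sim_params(n_genes = 300, g_global = 2, depth = 2e5,
                      n_replicates = 2, seed = 9)
  sim1 <- simulate_rna_experiment(p)
  sim2 <- simulate_rna_experiment(p)
  expect_identical(sim1$counts$counts, sim2$counts$counts)
  expect_true(all(colSums(sim1$counts$counts) == p$depth))
  # spikes constant, genes doubled: expected treated spike share is about
  # half the control share
  ex <- rna_expectation(p)
  spike_share <- colSums(ex$expected[ex$is_spike, ]) / p$depth
  ctrl <- ex$samples$condition == "control"
  ratio <- mean(spike_share[!ctrl]) / mean(spike_share[ctrl])
  # genes take 2G/(2G+S) of the treated library, so the share ratio is
  # (G+S)/(2G+S), slightly above 1/2 at spike mass 5% of gene mass
  expect_equal(ratio, (1 + 0.05) / (2 + 0.05), tolerance = 1e-10)
})

test_that("null RNA simulation has near-zero per-gene fold-changes", {
  # noise-free (multinomial) mode isolates the generator's mean structure
  p <- rna_sim_params(n_genes = 2000, g_global = 1, depth = 1e6,
                      n_replicates = 3, dispersion = 0, seed = 21)
  sim <- simulate_rna_experiment(p)
  m <- sim$counts$counts[!sim$counts$is_spike, ]
  ctrl <- sim$samples$condition == "control"
  keep <- rowSums(m == 0) == 0
  fc <- log2(rowMeans(m[keep, !ctrl]) / rowMeans(m[keep, ctrl]))
  expect_lt(median(abs(fc)), 0.05)
})

test_that("rna_sim_params validates dispersion and DE indices", {
  expect_error(rna_sim_params(dispersion = -1), "dispersion")
  expect_error(rna_sim_params(n_genes = 10,
                              de_spec = data.frame(gene = 11, log2fc = 1)),
               "out of range")
})

test_that("simulated annotations are reproducible and respect capacity", {
  g <- genome_index(c(chrT = 1e6))
  a1 <- simulate_annotations(g, n_tss = 10, n_repeats = 20,
                             gene_sets = c(target = 100), seed = 3)
  a2 <- simulate_annotations(g, n_tss = 10, n_repeats = 20,
                             gene_sets = c(target = 100), seed = 3)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$tss), 10)
  expect_true(all(a1$tss$end - a1$tss$start == 1))
  expect_true(all(a1$tss$strand %in% c("+", "-")))
  expect_equal(length(a1$gene_sets$target), 100)
  expect_equal(anyDuplicated(a1$gene_sets$target), 0)
  expect_true(all(a1$gene_sets$target %in% a1$universe))
  # repeats are non-overlapping
  r <- a1$repeats[order(a1$repeats$start), ]
  expect_true(all(head(r$end, -1) <= tail(r$start, -1)))
  expect_error(simulate_annotations(genome_index(c(c1 = 1000)),
                                    n_repeats = 500, seed = 1),
               "capacity")
})
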