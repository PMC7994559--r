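#' Parameters for an ERCC-spiked RNA-seq simulation
#'
#' Models a two-condition experiment in which the treated condition's
#' per-cell transcriptome is globally scaled by `g_global` while a constant
#' per-cell amount of exogenous spike-in RNA (ERCC-style, added per cell
#' equivalent) is present in every sample.  Sequencing at a fixed library
#' size erases the global scale from gene counts; only the gene:spike mix
#' retains it - the signal cell-number normalization recovers.
#'
#' @param n_genes number of endogenous genes.
#' @param n_spike_species number of spike-in species (default 92, the ERCC
#'   mix size).
#' @param g_global treated/control ratio of true per-cell transcriptome mass.
#' @param de_spec data frame with columns `gene` (index) and `log2fc`:
#'   genuinely differential genes, applied on top of the global scaling.
#' @param n_replicates samples per condition.
#' @param n_batches number of batches/litters; samples are assigned round
#'   robin within each condition.
#' @param batch_effect_sd SD (log2 scale) of per-gene, per-batch
#'   multiplicative offsets.  Spike rows are never touched by batch effects
#'   (spikes are added after lysis).
#' @param depth library size per sample (counts sum to this exactly).
#' @param dispersion negative-binomial-like overdispersion (0 = multinomial).
#' @param spike_mass_fraction total spike mass as a fraction of the control
#'   condition's gene mass (default 0.05).
#' @param seed master seed.
#' @return an `rna_sim_params` list.
#' @export
rna_sim_params <- function(n_genes = 2000, n_spike_species = 92,
                           g_global = 1, de_spec = NULL,
                           n_replicates = 3, n_batches = 1,
                           batch_effect_sd = 0, depth = 1e6,
                           dispersion = 0.05,
                           spike_mass_fraction = 0.05, seed = 1) {
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  assert_that(g_global > 0, "g_global must be positive")
  assert_that(n_batches >= 1 && n_batches <= n_replicates,
              "need 1 <= n_batches <= n_replicates")
  if (is.null(de_spec)) {
    de_spec <- data.frame(gene = integer(), log2fc = numeric())
  }
  de_spec <- as.data.frame(de_spec)
  if (nrow(de_spec) > 0) {
    assert_that(all(de_spec$gene >= 1) && all(de_spec$gene <= n_genes),
                "de_spec gene indices out of range")
    assert_that(!anyDuplicated(de_spec$gene), "duplicate de_spec genes")
  }
  structure(list(n_genes = n_genes, n_spike_species = n_spike_species,
                 g_global = g_global, de_spec = de_spec,
                 n_replicates = n_replicates, n_batches = n_batches,
                 batch_effect_sd = batch_effect_sd, depth = depth,
                 dispersion = dispersion,
                 spike_mass_fraction = spike_mass_fraction,
                 seed = as.integer(seed)),
            class = "rna_sim_params")
}

rna_sample_sheet <- function(params) {
  grid <- expand.grid(replicate = seq_len(params$n_replicates),
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_rep%d", grid$condition, grid$replicate)
  # round-robin batch assignment, balanced across conditions
  grid$batch <- sprintf("batch%d", ((grid$replicate - 1) %% params$n_batches) + 1)
  grid[, c("sample", "condition", "replicate", "batch")]
}

#' Closed-form expectations for an RNA simulation
#'
#' Per-sample expected counts for every gene and spike row, conditional on
#' the seed-determined abundances and batch offsets; no sampling.
#'
#' @param params an [rna_sim_params()].
#' @return list with `samples`, `expected` (rows x samples matrix of expected
#'   counts), `abundance` components and `is_spike`.
#' @export
rna_expectation <- function(params) {
  sheet <- rna_sample_sheet(params)
  base <- with_seed(child_seed(params$seed, 0L), {
    gene_ab <- rlnorm(params$n_genes, meanlog = 4, sdlog = 1.2)
    spike_ab <- rlnorm(params$n_spike_species, meanlog = 4, sdlog = 1.2)
    batch_off <- matrix(rnorm(params$n_genes * params$n_batches, 0,
                              params$batch_effect_sd),
                        params$n_genes, params$n_batches,
                        dimnames = list(NULL, sprintf("batch%d",
                                                      seq_len(params$n_batches))))
    list(gene_ab = gene_ab, spike_ab = spike_ab, batch_off = batch_off)
  })
  # scale spikes so their total mass is spike_mass_fraction of control gene mass
  base$spike_ab <- base$spike_ab *
    params$spike_mass_fraction * sum(base$gene_ab) / sum(base$spike_ab)
  de_mult <- rep(1, params$n_genes)
  if (nrow(params$de_spec) > 0) {
    de_mult[params$de_spec$gene] <- 2^params$de_spec$log2fc
  }
  rows <- c(sprintf("gene%05d", seq_len(params$n_genes)),
            sprintf("ERCC-%05d", seq_len(params$n_spike_species)))
  is_spike <- c(rep(FALSE, params$n_genes), rep(TRUE, params$n_spike_species))
  expected <- matrix(0, length(rows), nrow(sheet),
                     dimnames = list(rows, sheet$sample))
  for (i in seq_len(nrow(sheet))) {
    mult <- if (sheet$condition[i] == "treated") {
      params$g_global * de_mult
    } else {
      rep(1, params$n_genes)
    }
    gene_mass <- base$gene_ab * mult * 2^base$batch_off[, sheet$batch[i]]
    mass <- c(gene_mass, base$spike_ab)
    expected[, i] <- params$depth * mass / sum(mass)
  }
  list(samples = sheet, expected = expected, abundance = base,
       de_mult = de_mult, is_spike = is_spike)
}

#' Simulate an ERCC-spiked RNA-seq experiment
#'
#' Per-cell gene abundances are drawn once (log-normal) and shared by both
#' conditions; the treated condition's gene abundances are multiplied by
#' `g_global` and by any per-gene differential effects, while spike
#' abundances stay constant per cell.  Batch offsets act multiplicatively on
#' gene rows only.  Each library of exactly `depth` reads is drawn
#' multinomially from gamma-perturbed proportions, giving
#' negative-binomial-like overdispersion at the stated `dispersion` while
#' conserving the library size exactly.
#'
#' @param params an [rna_sim_params()].
#' @return list with `counts` (a `ss_count_matrix` with flagged spike rows),
#'   `samples` (sample sheet) and `truth` (`sim_truth` manifest).
#' @export
simulate_rna_experiment <- function(params) {
  assert_that(inherits(params, "rna_sim_params"),
              "params must come from rna_sim_params()")
  expect <- rna_expectation(params)
  sheet <- expect$samples
  counts <- matrix(0L, nrow(expect$expected), ncol(expect$expected),
                   dimnames = dimnames(expect$expected))
  for (i in seq_len(nrow(sheet))) {
    p <- expect$expected[, i] / params$depth
    counts[, i] <- with_seed(child_seed(params$seed, i), {
      w <- if (params$dispersion > 0) {
        shape <- 1 / params$dispersion
        rgamma(length(p), shape = shape, rate = shape) * p
      } else p
      rmultinom(1, params$depth, w)[, 1]
    })
  }
  cm <- count_matrix(counts, spike_prefix = "ERCC-")
  truth <- structure(list(kind = "rna", params = params,
                          expected = expect$expected,
                          samples = sheet,
                          de_mult = expect$de_mult,
                          seed = params$seed),
                     class = "sim_truth")
  ss_log("simulate_rna_experiment: %d genes + %d spikes x %d samples, depth %g, g_global %g, seed %d",
         params$n_genes, params$n_spike_species, nrow(sheet), params$depth,
         params$g_global, params$seed)
  list(counts = cm, samples = sheet, truth = truth)
}
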