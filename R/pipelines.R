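#' Pipeline configuration
#'
#' Builds a fully resolved configuration for the two study pipelines.  All
#' thresholds default to the study values; unknown keys are rejected so a
#' typo cannot silently fall back to a default.  Configurations can also be
#' read from a YAML file.  Every pipeline run writes the resolved
#' configuration beside its outputs.
#'
#' @param pipeline `"chip"` or `"rna"`.
#' @param overrides named list of overrides (nested lists allowed), e.g.
#'   `list(simulate = list(r_global = 0.5), seed = 7)`.
#' @return the resolved configuration list.
#' @export
pipeline_config <- function(pipeline = c("chip", "rna"), overrides = list()) {
  pipeline <- match.arg(pipeline)
  defaults <- if (pipeline == "chip") {
    list(
      seed = 1,
      outdir = "results/chip",
      inputs = list(species_counts = NULL, ip_bins = NULL,
                    input_bins = NULL),
      simulate = list(n_bins = 5000, bin_width = 10000, r_global = 0.5,
                      spike_fraction = 0.05, depth = 1e6, n_replicates = 3,
                      domain_start_bin = 1000, domain_n_bins = 30,
                      domain_multiplier = 3),
      pseudocount = 0.5,
      gap_bins = 3,
      q_threshold = 0.05,
      merge_distance = 3000,
      depth_normalize = FALSE,
      repeat_min_hyper = 5,
      repeat_max_hypo = 3,
      repeat_log2_threshold = 0.7,
      promoter_upstream = 10000,
      promoter_downstream = 1000,
      n_components = 2,
      n_repeats = 100,
      n_tss = 100
    )
  } else {
    list(
      seed = 1,
      outdir = "results/rna",
      inputs = list(counts = NULL, sample_sheet = NULL),
      spike_prefix = "ERCC-",
      simulate = list(n_genes = 2000, g_global = 2, n_replicates = 3,
                      depth = 1e6, dispersion = 0.05, n_batches = 1,
                      batch_effect_sd = 0, n_de = 0, de_log2fc = 2),
      filter_mode = "es",
      cpm_threshold = 3,
      cpm_rule = "all",
      min_total = 10,
      prior = 0.5,
      alpha = 0.05,
      lfc_threshold = 0.7,
      litter_padj_cutoff = 0.1,
      geneset_seed = 1,
      geneset_size = 100
    )
  }
  merge_config(defaults, overrides, path = pipeline)
}

merge_config <- function(defaults, overrides, path) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    ss_abort(sprintf("unknown config key: %s.%s", path, unknown[1]),
             "spikeshift_config_error")
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste(path, nm, sep = "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' @rdname pipeline_config
#' @param path YAML file with a top-level `pipeline:` key plus overrides.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  assert_that(!is.null(raw$pipeline), "config must name a pipeline",
              "spikeshift_config_error")
  pipeline <- raw$pipeline
  raw$pipeline <- NULL
  pipeline_config(pipeline, raw)
}

write_resolved_config <- function(config, pipeline, outdir) {
  yaml::write_yaml(c(list(pipeline = pipeline), config),
                   file.path(outdir, "config_resolved.yaml"))
}

#' Run the spike-in ChIP-seq pipeline
#'
#' Orchestrates the ChIP stages in order: normalization factors, NF
#' scaling, binned enrichment, ECDF/KS comparison, broad-domain calling
#' per replicate with 3 kb merge and replicate intersection, repeat-element
#' classification, region quantification and PCA.  Inputs are either the
#' TSV paths in `config$inputs` or (default) a simulation drawn from
#' `config$simulate`.  Every artifact is written under `config$outdir`
#' together with a manifest of factors and seeds; re-running with an
#' identical config reproduces the outputs bit-identically.
#'
#' @param config from [pipeline_config()] (`"chip"`).
#' @return the output directory, invisibly; artifact paths as attribute.
#' @export
run_chip_pipeline <- function(config = pipeline_config("chip")) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$inputs$species_counts)) {
    for (f in unlist(config$inputs)) {
      assert_that(file.exists(f), sprintf("missing input: %s", f),
                  "spikeshift_data_error")
    }
    species <- read.delim(config$inputs$species_counts, sep = "\t")
    ip_bins <- read_bin_counts(config$inputs$ip_bins)
    input_bins <- read_bin_counts(config$inputs$input_bins)
    genome <- genome_index(tapply(ip_bins$bins$end, ip_bins$bins$chrom, max))
    truth <- NULL
  } else {
    sim_cfg <- config$simulate
    dom <- if (sim_cfg$domain_n_bins > 0) {
      data.frame(start_bin = sim_cfg$domain_start_bin,
                 n_bins = sim_cfg$domain_n_bins,
                 multiplier = sim_cfg$domain_multiplier)
    } else NULL
    params <- chip_sim_params(n_bins = sim_cfg$n_bins,
                              bin_width = sim_cfg$bin_width,
                              domain_spec = dom,
                              r_global = sim_cfg$r_global,
                              spike_fraction = sim_cfg$spike_fraction,
                              depth = sim_cfg$depth,
                              n_replicates = sim_cfg$n_replicates,
                              seed = config$seed)
    sim <- simulate_chip_experiment(params)
    species <- sim$species_counts
    ip_bins <- sim$ip_bins
    input_bins <- sim$input_bins
    genome <- sim$genome
    truth <- sim$truth
  }
  conds <- unique(species$condition[species$role == "IP"])
  assert_that(length(conds) == 2, "expected exactly two conditions",
              "spikeshift_data_error")

  # 1. normalization factors
  nfs <- compute_spikein_nfs(species)
  write.table(nfs, file.path(outdir, "normalization_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # 2. NF-scaled bins (+ input scaled to unity NFs)
  ip_scaled <- scale_bin_counts(ip_bins, nfs,
                                depth_normalize = config$depth_normalize)
  input_nfs <- data.frame(sample = colnames(input_bins$counts), nf = 1)
  input_scaled <- scale_bin_counts(input_bins, input_nfs,
                                   depth_normalize = config$depth_normalize)
  write_bin_counts(ip_scaled, file.path(outdir, "scaled_bins.tsv"))
  write_bedgraph(ip_scaled, colnames(ip_scaled$counts)[1],
                 file.path(outdir, "scaled_sample1.bedgraph"))

  # 3. enrichment distributions + KS
  splits <- lapply(conds, function(cn) {
    ip_cols <- grepl(paste0("^", cn, "_"), colnames(ip_scaled$counts))
    in_cols <- grepl(paste0("^", cn, "_"), colnames(input_scaled$counts))
    enrichment_distribution(
      bin_matrix(ip_scaled$bins, ip_scaled$counts[, ip_cols, drop = FALSE]),
      bin_matrix(input_scaled$bins,
                 input_scaled$counts[, in_cols, drop = FALSE]),
      pseudocount = config$pseudocount, label = cn)
  })
  names(splits) <- conds
  ks <- ks_compare(splits[[1]], splits[[2]])
  ecdf_tab <- do.call(rbind, lapply(splits, function(e)
    data.frame(condition = e$label, value = e$values)))
  write.table(ecdf_tab, file.path(outdir, "enrichment_values.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(condition_a = conds[1], condition_b = conds[2],
                         D = ks$D, p = ks$p),
              file.path(outdir, "ks_test.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # 4. broad domains per replicate, merged and intersected
  rep_domains <- lapply(1:2, function(r) {
    ipc <- grepl(sprintf("rep%d_IP$", r), colnames(ip_scaled$counts))
    inc <- grepl(sprintf("rep%d_input$", r), colnames(input_scaled$counts))
    if (!any(ipc)) return(intervals(character(), numeric(), numeric()))
    call_broad_domains(
      bin_matrix(ip_scaled$bins, ip_scaled$counts[, ipc, drop = FALSE]),
      bin_matrix(input_scaled$bins,
                 input_scaled$counts[, inc, drop = FALSE]),
      gap_bins = config$gap_bins, q_threshold = config$q_threshold)
  })
  domains <- merge_and_intersect(rep_domains[[1]], rep_domains[[2]],
                                 merge_distance = config$merge_distance)
  write_bed(domains, file.path(outdir, "domains.bed"))

  # 5. repeats + region counts over simulated annotations
  anno <- simulate_annotations(genome, n_tss = config$n_tss,
                               n_repeats = config$n_repeats,
                               seed = config$seed)
  rep_counts <- region_counts(ip_scaled, anno$repeats)
  cond_cols <- function(m, cn) rowMeans(m[, grepl(paste0("^", cn, "_"),
                                                  colnames(m)),
                                          drop = FALSE])
  calls <- classify_repeat_elements(
    high = cond_cols(rep_counts, conds[2]),
    ctrl = cond_cols(rep_counts, conds[1]),
    elements = anno$repeats$name,
    min_hyper = config$repeat_min_hyper,
    max_hypo = config$repeat_max_hypo,
    log2_threshold = config$repeat_log2_threshold)
  write.table(calls, file.path(outdir, "repeat_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prom <- promoter_windows(anno$tss, config$promoter_upstream,
                           config$promoter_downstream, genome)
  prom_counts <- region_counts(ip_scaled, prom, input = input_scaled,
                               average_replicates = TRUE)
  write.table(data.frame(region = rownames(prom_counts), prom_counts,
                         check.names = FALSE),
              file.path(outdir, "promoter_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. PCA on log-scale enrichment per replicate
  log_bins <- log2(ip_scaled$counts + 1)
  pca <- pca_embed(log_bins, n_components = config$n_components)
  write.table(data.frame(sample = rownames(pca$coords), pca$coords,
                         check.names = FALSE),
              file.path(outdir, "pca_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(seed = config$seed,
                   normalization_factors = setNames(nfs$nf, nfs$sample),
                   ks = ks[c("D", "p")],
                   n_domains = nrow(domains))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  write_resolved_config(config, "chip", outdir)
  if (!is.null(truth)) write_sim_truth(truth, file.path(outdir,
                                                        "sim_truth.json"))
  ss_log("run_chip_pipeline: wrote %s", outdir)
  invisible(structure(outdir, artifacts = list.files(outdir)))
}

#' Run the CNN RNA-seq pipeline
#'
#' Filter, ERCC normalization factors, CNN log expression, differential
#' expression (moderated t in ES mode; litter-matched NB overlap in embryo
#' mode), global-shift summary and a gene-set shift against a seeded random
#' subset.  Artifacts and a manifest are written under `config$outdir`.
#'
#' @param config from [pipeline_config()] (`"rna"`).
#' @return the output directory, invisibly.
#' @export
run_rna_pipeline <- function(config = pipeline_config("rna")) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$inputs$counts)) {
    assert_that(file.exists(config$inputs$counts),
                sprintf("missing input: %s", config$inputs$counts),
                "spikeshift_data_error")
    counts <- read_counts_table(config$inputs$counts,
                                spike_prefix = config$spike_prefix)
    sheet <- read.delim(config$inputs$sample_sheet, sep = "\t")
    missing <- setdiff(colnames(counts$counts), sheet$sample)
    assert_that(length(missing) == 0,
                sprintf("sample sheet missing sample: %s", missing[1]),
                "spikeshift_data_error")
    sheet <- sheet[match(colnames(counts$counts), sheet$sample), ]
    truth <- NULL
  } else {
    sim_cfg <- config$simulate
    de <- if (sim_cfg$n_de > 0) {
      data.frame(gene = seq_len(sim_cfg$n_de), log2fc = sim_cfg$de_log2fc)
    } else NULL
    params <- rna_sim_params(n_genes = sim_cfg$n_genes,
                             g_global = sim_cfg$g_global,
                             de_spec = de,
                             n_replicates = sim_cfg$n_replicates,
                             n_batches = sim_cfg$n_batches,
                             batch_effect_sd = sim_cfg$batch_effect_sd,
                             depth = sim_cfg$depth,
                             dispersion = sim_cfg$dispersion,
                             seed = config$seed)
    sim <- simulate_rna_experiment(params)
    counts <- sim$counts
    sheet <- sim$samples
    truth <- sim$truth
  }
  filtered <- filter_low_expression(counts, mode = config$filter_mode,
                                    cpm_threshold = config$cpm_threshold,
                                    cpm_rule = config$cpm_rule,
                                    min_total = config$min_total)
  factors <- cnn_norm_factors(filtered)
  write.table(factors, file.path(outdir, "cnn_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logexpr <- cnn_log_expression(filtered, factors, prior = config$prior)
  write.table(data.frame(gene = rownames(logexpr), logexpr,
                         check.names = FALSE),
              file.path(outdir, "cnn_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  treated <- sheet$sample[sheet$condition != sheet$condition[1]]
  control <- sheet$sample[sheet$condition == sheet$condition[1]]
  if (config$filter_mode == "embryo") {
    de_res <- litter_matched_de(filtered, sheet$batch, sheet$condition,
                                padj_cutoff = config$litter_padj_cutoff)
    writeLines(de_res$up, file.path(outdir, "up_genes.txt"))
    writeLines(de_res$down, file.path(outdir, "down_genes.txt"))
    for (l in names(de_res$per_litter)) {
      write.table(de_res$per_litter[[l]],
                  file.path(outdir, sprintf("de_table_%s.tsv", l)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    groups <- factor(ifelse(sheet$sample %in% treated, "treated", "control"),
                     levels = c("control", "treated"))
    de_tab <- moderated_de(logexpr, groups, alpha = config$alpha,
                           lfc_threshold = config$lfc_threshold)
    write.table(de_tab, file.path(outdir, "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  shift <- global_shift(logexpr, treated, control)
  write.table(data.frame(stat = names(shift$summary),
                         value = unname(shift$summary)),
              file.path(outdir, "global_shift.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  universe <- rownames(logexpr)
  target <- random_subset(universe, min(config$geneset_size,
                                        length(universe)),
                          seed = config$geneset_seed)
  background <- random_subset(universe, min(config$geneset_size,
                                            length(universe)),
                              seed = config$geneset_seed + 1)
  gshift <- geneset_shift(shift$fc, list(target = target,
                                         background = background))
  write.table(gshift$summaries, file.path(outdir, "geneset_shift.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(seed = config$seed,
                   cnn_factors = setNames(factors$nf, factors$sample),
                   median_global_log2fc = unname(shift$summary["median"]),
                   global_shift_p = shift$p)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  write_resolved_config(config, "rna", outdir)
  if (!is.null(truth)) write_sim_truth(truth, file.path(outdir,
                                                        "sim_truth.json"))
  ss_log("run_rna_pipeline: wrote %s", outdir)
  invisible(structure(outdir, artifacts = list.files(outdir)))
}
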