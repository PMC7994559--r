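test_that("unknown config keys are rejected with the offending name", {
  expect_error(pipeline_config("chip", list(nonsense = 1)),
               "chip.nonsense", class = "spikeshift_config_error")
  expect_error(pipeline_config("rna", list(simulate = list(bogus = 2))),
               "rna.simulate.bogus", class = "spikeshift_config_error")
})

test_that("YAML configs resolve against the defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pipeline: chip", "seed: 9",
               "simulate:", "  n_bins: 500"), f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$simulate$n_bins, 500)
  expect_equal(cfg$gap_bins, 3)          # untouched default
})

test_that("the ChIP pipeline runs end to end and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  ov <- list(simulate = list(n_bins = 800, depth = 2e5,
                             domain_start_bin = 200, domain_n_bins = 20),
             seed = 5)
  suppressMessages(run_chip_pipeline(pipeline_config("chip",
                                                     c(ov, outdir = out1))))
  suppressMessages(run_chip_pipeline(pipeline_config("chip",
                                                     c(ov, outdir = out2))))
  expected <- c("normalization_factors.tsv", "scaled_bins.tsv",
                "scaled_sample1.bedgraph", "enrichment_values.tsv",
                "ks_test.tsv", "domains.bed", "repeat_calls.tsv",
                "promoter_counts.tsv", "pca_coordinates.tsv",
                "manifest.yaml", "config_resolved.yaml")
  expect_true(all(expected %in% list.files(out1)))
  for (f in setdiff(expected, "config_resolved.yaml")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("a missing input file halts the ChIP pipeline by name", {
  cfg <- pipeline_config("chip", list(
    outdir = withr::local_tempdir(),
    inputs = list(species_counts = "absent_species.tsv",
                  ip_bins = "absent_ip.tsv",
                  input_bins = "absent_input.tsv")))
  expect_error(suppressMessages(run_chip_pipeline(cfg)),
               "absent_species", class = "spikeshift_data_error")
})

test_that("the RNA pipeline runs in ES mode and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  ov <- list(simulate = list(n_genes = 600, depth = 2e5), seed = 8)
  suppressMessages(run_rna_pipeline(pipeline_config("rna",
                                                    c(ov, outdir = out1))))
  suppressMessages(run_rna_pipeline(pipeline_config("rna",
                                                    c(ov, outdir = out2))))
  expected <- c("cnn_factors.tsv", "cnn_matrix.tsv", "de_table.tsv",
                "global_shift.tsv", "geneset_shift.tsv", "manifest.yaml",
                "config_resolved.yaml")
  expect_true(all(expected %in% list.files(out1)))
  for (f in setdiff(expected, "config_resolved.yaml")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("embryo mode emits per-litter tables consistent with the sets", {
  out <- withr::local_tempdir()
  cfg <- pipeline_config("rna", list(
    outdir = out, seed = 3, filter_mode = "embryo",
    simulate = list(n_genes = 400, depth = 2e5, n_replicates = 6,
                    n_batches = 2, batch_effect_sd = 0.25, n_de = 5,
                    de_log2fc = 3, g_global = 1)))
  suppressMessages(run_rna_pipeline(cfg))
  up <- readLines(file.path(out, "up_genes.txt"))
  for (l in c("batch1", "batch2")) {
    tab <- read.delim(file.path(out, sprintf("de_table_%s.tsv", l)))
    sig_up <- tab$gene[tab$padj < 0.1 & tab$log2fc > 0]
    expect_true(all(up %in% sig_up))
  }
})
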