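#!/usr/bin/env Rscript
# Generate the synthetic study data every later step consumes: a spike-in
# ChIP-seq experiment in which the treated cells carry half the per-cell
# H3K27me3 of controls (plus one implanted broad domain), and an
# ERCC-spiked RNA-seq experiment in which the treated transcriptome is
# globally doubled.  Written as plain-text fixtures under results/data/.

library(spikeshift)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924

chip <- simulate_chip_experiment(chip_sim_params(
  n_bins = 5000, bin_width = 10000, depth = 1e6, n_replicates = 3,
  r_global = 0.5,
  domain_spec = data.frame(start_bin = 1000, n_bins = 30, multiplier = 3),
  seed = seed))
write.table(chip$species_counts, file.path(outdir, "chip_species_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bin_counts(chip$ip_bins, file.path(outdir, "chip_ip_bins.tsv"))
write_bin_counts(chip$input_bins, file.path(outdir, "chip_input_bins.tsv"))
write_chrom_sizes(chip$genome, file.path(outdir, "target.chrom.sizes"))
write_sim_truth(chip$truth, file.path(outdir, "chip_truth.json"))

rna <- simulate_rna_experiment(rna_sim_params(
  n_genes = 2000, g_global = 2, depth = 1e6, n_replicates = 3,
  de_spec = data.frame(gene = 1:20, log2fc = 2), seed = seed))
write_counts_table(rna$counts, file.path(outdir, "rna_counts.tsv"))
write.table(rna$samples, file.path(outdir, "rna_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_sim_truth(rna$truth, file.path(outdir, "rna_truth.json"))

anno <- simulate_annotations(chip$genome, n_tss = 200, n_repeats = 150,
                             gene_sets = c(prc2_targets = 150), seed = seed)
write_bed(anno$tss, file.path(outdir, "tss.bed"))
write_bed(anno$repeats, file.path(outdir, "repeats.bed"))
writeLines(anno$gene_sets$prc2_targets,
           file.path(outdir, "prc2_target_genes.txt"))

cat(sprintf("ChIP: %d bins x %d samples at depth 1e6 (true r = 0.5)\n",
            nrow(chip$ip_bins$counts),
            ncol(chip$ip_bins$counts) + ncol(chip$input_bins$counts)))
cat(sprintf("RNA:  %d genes + %d spikes x %d samples (true g = 2)\n",
            sum(!rna$counts$is_spike), sum(rna$counts$is_spike),
            ncol(rna$counts$counts)))
cat(sprintf("Fixtures written to %s\n", outdir))
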