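#!/usr/bin/env Rscript
# The quantitative ChIP-seq stack on the simulated experiment: spike-in
# normalization factors, NF-scaled binned enrichment, ECDF/KS landscape
# comparison, broad-domain calling with 3 kb merge and replicate
# intersection, repeat classification and PCA.  Runs the whole pipeline
# from one config and then restates the findings that matter.

library(spikeshift)

cfg <- pipeline_config("chip", list(
  outdir = "results/02_chip",
  seed = 20260924,
  simulate = list(r_global = 0.5, domain_start_bin = 1000,
                  domain_n_bins = 30, domain_multiplier = 3)))
run_chip_pipeline(cfg)

nfs <- read.delim("results/02_chip/normalization_factors.tsv")
means <- tapply(nfs$nf, nfs$condition, mean)
ks <- read.delim("results/02_chip/ks_test.tsv")
domains <- read_bed("results/02_chip/domains.bed")
repeats <- read.delim("results/02_chip/repeat_calls.tsv")

cat(sprintf("Condition-mean NFs: control %.3f, treated %.3f (ratio %.3f; true r = 0.5)\n",
            means[["control"]], means[["treated"]],
            means[["treated"]] / means[["control"]]))
cat(sprintf("KS on per-bin enrichment: D = %.3f, p = %.3g -> the treated\n",
            ks$D, ks$p))
cat("  landscape is globally left-shifted, the signature of a per-cell loss\n")
cat("  that per-library scaling would have erased.\n")
cat(sprintf("Broad domains called (replicate-intersected, 3 kb merge): %d\n",
            nrow(domains)))
if (nrow(domains) > 0) {
  cat(sprintf("  spanning %s:%d-%d (implanted truth: chrT:9990000-10290000)\n",
              domains$chrom[1], min(domains$start), max(domains$end)))
}
cat(sprintf("Repeat elements: %d hyper / %d hypo / %d neither\n",
            sum(repeats$class == "hyper"), sum(repeats$class == "hypo"),
            sum(repeats$class == "neither")))
cat("Artifacts under results/02_chip/\n")
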