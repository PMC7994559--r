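# spikeshift

Spike-in-calibrated detection of global chromatin and transcription shifts.

Fixed-depth sequencing normalizes every library to the same size, so a
change that moves the *whole* genome or transcriptome — a genome-wide loss
of H3K27me3 during the naive-to-primed pluripotency transition, global
hyper- or hypotranscription after perturbing a chromatin regulator — is
erased by standard per-library scaling. `spikeshift` implements the two
quantitative pipelines that recover such shifts from internal rulers:

* **ChIP-seq with exogenous-genome spike-in.** Per-sample normalization
  factors are the target/spike read ratio of the IP taken as a fraction of
  its matched input, `NF = (t_IP/s_IP) / (t_in/s_in)` — depth-invariant and
  proportional to true per-cell signal mass. Downstream: NF-scaled 10 kb
  bin counts, cumulative-enrichment distributions of
  `log2(IP/input + 0.5)` with two-sample Kolmogorov–Smirnov comparison,
  empirical-Bayes batch adjustment with PCA, a calibrated Poisson
  broad-domain caller with bedtools-style post-processing (3 kb merge,
  replicate intersection), promoter/bivalent-window quantification and
  repeat-element classification.
* **Cell-number-normalized (CNN) RNA-seq with ERCC spike-ins.** Per-sample
  factors from trimmed-mean-of-M-values applied to spike rows only with
  library sizes fixed to the gene-count sums `N`; CNN log2 expression
  `log2((count + 0.5)/(N·nf + 1) × 1e6)`; moderated-t differential
  expression (adjusted p < 0.05, |log2FC| > 0.7) with optional
  mean–variance precision weights; global-shift summaries with Wilcoxon
  rank-sum tests; and litter-matched negative-binomial DE overlap for the
  embryo arm.
* **Gene-set machinery**: Fisher-exact overlap enrichment over an explicit
  universe, percent-overlap reporting, seeded random subsets, and
  target-vs-background fold-change shifts.
* **A synthetic-data generator** with known ground truth (global scale
  factors, implanted broad domains, differential genes, batch effects)
  that makes every stage testable without sequencing data.

## Worked example

Simulate an experiment in which treated cells carry half the per-cell
H3K27me3 of controls, then recover that factor from the species-split read
counts alone:

```r
library(spikeshift)
sim <- simulate_chip_experiment(chip_sim_params(
  n_bins = 5000, depth = 1e6, n_replicates = 3, r_global = 0.5,
  seed = 20260924))
nfs <- compute_spikein_nfs(sim$species_counts)
tapply(nfs$nf, nfs$condition, mean)
#>   control   treated
#> 0.9996753 0.5001717
```

The condition-mean NF ratio (0.500) recovers the simulated per-cell ratio;
each library still has exactly 1e6 reads, so no per-library method could
have seen it. The same experiment's enrichment landscape shifts left
(`analysis/02_chip_spikein_analysis.R` prints `KS D = 0.994, p = 0`), and
the implanted 30-bin broad domain is recovered exactly
(`chrT:9990000-10290000`).

On the RNA side, a global doubling of the treated transcriptome
(`g_global = 2`) gives (from `analysis/03_rna_cnn_analysis.R`):

```
Median log2FC  (CNN):   +1.011  (true global log2 ratio: +1)
Median log2FC  (naive): -0.023  (global doubling invisible)
```

and the worked gene-set example reports `248/277 = 89.53%, reported 90%`.

## Analysis workflow

The numbered scripts under `analysis/` re-run the study arms on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | generate the ChIP and RNA experiments + annotations |
| `02_chip_spikein_analysis.R` | NFs, scaled bins, ECDF/KS, domains, repeats, PCA |
| `03_rna_cnn_analysis.R` | CNN factors and expression, DE, CNN-vs-naive contrast |
| `04_embryo_litter_de.R` | litter-matched NB differential expression overlap |
| `05_gene_set_analysis.R` | Fisher overlap, percent overlap, gene-set shift |

Each is a thin driver over the exported functions; `run_chip_pipeline()`
and `run_rna_pipeline()` execute a whole arm from one (YAML-able) config
with every threshold as a key and paper-era defaults.

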