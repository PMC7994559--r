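---
title: "Detecting global chromatin and transcription shifts with spike-in calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting global chromatin and transcription shifts with spike-in calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeshift)
options(spikeshift.log_level = "NONE")
```

## The problem

Standard sequencing normalization scales every library to the same size, so
a change that affects the whole genome or the whole transcriptome uniformly
— a global loss of a histone mark, a genome-wide increase in
transcriptional output — is mathematically erased before analysis begins.
Biology does produce such shifts: the transition between naive
(preimplantation-like) and primed (postimplantation-like) pluripotent cell
states involves a genome-wide redistribution of the Polycomb mark H3K27me3
from diffuse broad domains to focal promoter peaks, together with
hyper-/hypotranscription of the whole transcriptome. Seeing these shifts
requires an internal ruler that does not scale with the cells under study:
exogenous chromatin from a second species spiked into each ChIP, and
exogenous ERCC RNA added per cell equivalent before library preparation.

`spikeshift` implements the two calibrated pipelines around these rulers,
plus a synthetic-data generator with known ground truth so that every stage
is testable without any sequencing data.

## Spike-in ChIP-seq normalization

Each IP and its matched input are aligned to a combined target + spike
reference, giving per-sample species-split read totals
$(t_{IP}, s_{IP}, t_{in}, s_{in})$. The normalization factor is the
target/spike enrichment of the IP taken as a fraction of input:

$$\mathrm{NF} \;=\; \frac{t_{IP}/s_{IP}}{t_{in}/s_{in}}.$$

Because the spike chromatin mass is the same in every IP while the target
chromatin mass per cell varies with the biology, the NF is proportional to
the true per-cell signal mass: it is invariant to uniform depth rescaling
of either sample (both counts scale together) and equals 1 when the IP
enriches target over spike no more than input does. Dividing by the input
ratio removes genome-size and mixing-ratio constants, so *ratios of NFs
across conditions* estimate the ratio of per-cell signal. `compute_spikein_nf()`
implements exactly this ratio-of-ratios; a subtraction-based reading of
"fraction of input" would not be depth-invariant, which is why the ratio
form was chosen.

Binned counts (non-overlapping 10 kb bins by default) are multiplied by the
sample's NF (`scale_bin_counts()`); a `depth_normalize` flag first converts
to counts per million of the target depth for unequal-depth designs, but
the default multiplies raw counts only, matching the convention of scaling
coverage tracks by a single factor.

## Binned enrichment, ECDF comparison and batch structure

For landscape-level comparisons, replicate columns are averaged and each
bin is summarised as $\log_2(\mathrm{IP}/\mathrm{input} + 0.5)$
(`enrichment_distribution()`). The pseudocount is added to the *ratio*, so
a zero-IP bin maps to $\log_2 0.5 = -1$; bins with zero input cannot form a
ratio and are dropped and tallied, mirroring the upstream removal of
regions without coverage. The placement of the pseudocount is genuinely
ambiguous in the figure axis label it reproduces; adding it to the ratio
keeps the value finite for zero IP while leaving well-covered bins
essentially untouched, and is exposed as a parameter.

Two conditions are compared by the two-sample two-sided Kolmogorov–Smirnov
test on these per-bin values (`ks_compare()`, backed by `stats::ks.test`
and verified in the tests against an exhaustive threshold scan). A global
per-cell loss shows up as a left-shifted ECDF — stochastic dominance,
not just a mean difference.

When samples from different experimental origins are pooled, per-bin
log-scale values are adjusted for batch with a location/scale model
(`batch_adjust()`): features are standardized to pooled mean and variance,
per-batch location and scale parameters are estimated and shrunk toward
their across-feature means with parametric empirical-Bayes priors (normal
for locations, inverse-gamma for scales), then regressed out. With
`shrink = FALSE` the raw estimates are used and per-feature batch means are
removed exactly — the mode the exactness tests use. The implementation is
cross-checked against `sva::ComBat` to near machine precision in the test
suite. `pca_embed()` then embeds samples (replicates kept separate) with a
fixed sign convention — the largest-magnitude loading of each component is
made positive — so repeated runs are bit-identical.

## Broad domains and post-processing

The broad-domain caller is deliberately simple: per bin, a one-sided
Poisson upper-tail test of the IP count against an expected count derived
from the input, Benjamini–Hochberg control across bins, and chaining of
significant bins into domains bridging up to `gap_bins` (default 3)
non-significant bins. The expected count is, per bin, the maximum of the
bin-level input, a `background_window` (default 51-bin) running mean of the
input, and the chromosome-wide mean, rescaled to the IP total. Taking the
maximum of local and global estimates biases the expectation upward, which
keeps the test conservative even though the input is itself a noisy counted
sample; a pure bin-level (or pure smoothed) expectation is measurably
anti-conservative on null simulations. This is the local-lambda convention
of established peak callers, re-derived here because the caller must be
self-contained and calibrated.

Post-processing follows the study's recipe exactly: within each replicate,
peaks separated by at most 3 kb are merged (a gap of exactly 3000 bases
merges, matching `bedtools merge -d` semantics), and the reported set is
the intersection of the merged replicates (`merge_and_intersect()`, built
on GenomicRanges; idempotent, order-invariant, sorted and disjoint by
construction).

Region-level quantification (`region_counts()`) sums bin signal weighted by
overlap fraction, so any tiling of the genome conserves total signal;
normalization is by spike NF for the cell-culture arm and by library size
for the embryo arm, with optional division by matched input and replicate
averaging. Promoter windows are strand-aware slop extensions (10 kb
upstream / 1 kb downstream for the generous promoter windows; 1 kb / 100 bp
for the bivalent-promoter variant), clamped to the chromosome. Repeat
elements are classified as hyper when $\log_2(\mathrm{high/ctrl}) > 0.7$
with high-condition signal above 5 normalized counts, hypo when
$\log_2 < -0.7$ with signal below 3, otherwise neither; the figure legend
quoting $|\log_2(0.7)|$ conflicts with the stated threshold of 0.7 on the
log2 scale, so 0.7 is the default and the value is configurable.

## Cell-number-normalized RNA-seq

Raw counts are split into gene and ERCC rows. After filtering (ES mode:
genes with a zero in any sample, or at most 3 CPM in every sample, are
dropped — read as "a gene survives if any sample exceeds the threshold",
the standard filtering idiom the wording paraphrases, with an `any/all`
switch exposed; embryo mode: fewer than 10 raw counts in total), per-sample
factors are computed by the trimmed-mean-of-M-values scheme applied to
spike rows only, with library sizes fixed to the gene-count sums $N$
(`cnn_norm_factors()`). The reference sample is the one whose
upper-quartile spike expression is closest to the mean; M-values are
trimmed 30%, A-values 5%, and the surviving M-values are averaged with
inverse-asymptotic-variance weights; factors are centered to geometric
mean 1. The implementation is verified against both a brute-force
enumeration oracle (to 1e-10) and the reference edgeR implementation
(to 1e-12) in the tests.

CNN log expression is the voom-style transform with effective library
sizes $N \cdot nf$:

$$\mathrm{CNN}_{gj} = \log_2\!\left(\frac{c_{gj} + 0.5}{N_j\,nf_j + 1}\times 10^6\right).$$

Under a pure global scaling $g$ of the treated transcriptome with constant
spikes, the treated spike share of a fixed-size library shrinks by the same
factor the gene share grows, the TMM-on-spikes factor absorbs it, and the
median CNN log2 fold-change recovers $\log_2 g$ exactly in expectation,
while naive per-million normalization returns 0 — the identifiability
contrast the acceptance checks measure.

## Differential expression

`moderated_de()` fits the per-gene two-group contrast on CNN log
expression and shrinks residual variances by empirical Bayes: prior
degrees of freedom $d_0$ and prior variance $s_0^2$ are obtained by moment
matching of the log-variance distribution under a scaled-F model
(trigamma inversion), the posterior variance is
$(d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated t carries $d_0 + d$
degrees of freedom (capped at the pooled residual df). `prior_df = 0`
recovers the ordinary equal-variance t-test, and the whole fit is verified
against `limma::eBayes` in the tests. Significance uses the study
thresholds: adjusted $p < 0.05$ and $|\log_2 FC| > 0.7$, BH-adjusted
("adjusted P" is otherwise unspecified, and BH is the field default).

Optional per-observation precision weights from a fitted mean–variance
trend are available (`voom_weights()`, verified against `limma::voom`) and
are off by default, since the original transformation is cited chiefly for
its effective library sizes. The weights matter in one specific corner: a
single shared variance prior over-shrinks the (higher) variance of
low-count genes, and on null simulations roughly one seed in six then shows
a single low-count gene slipping past the combined threshold. The nominal
type-I error stays within [0.03, 0.07] either way; with weights the
combined threshold is clean in ≥ 95% of null seeds. Both modes are tested
for exactly what they deliver.

The global-shift summary reports per-gene log2 fold-changes (mean treated
minus mean control on the CNN log scale) with boxplot statistics (hinges =
quartiles, whiskers ± 1.5 IQR) and a two-sided Wilcoxon rank-sum test of
the fold-change list against a zero-centered null list built from a
control-vs-control split; a fully tied comparison is reported as $p = 1$.

For embryo counts, `litter_matched_de()` runs a self-contained
negative-binomial Wald test within each litter — median-of-ratios size
factors, method-of-moments dispersions shrunk on the log scale toward a
fitted $a_0 + a_1/\mu$ trend (trend weight 4 relative to the per-gene
residual df), delta-method standard errors
$\mathrm{var}(\log \mu_k) \approx (1/\mu_k + \alpha)/n_k$ — applies the
adjusted $p < 0.1$ cutoff, and intersects direction-consistent per-litter
gene lists. The test is calibrated rather than engine-identical to the
original tool, which is the acceptance standard set for this stage.

## Gene-set analyses

`fisher_overlap()` tests each annotation against a query over an explicit
universe with the one-sided hypergeometric tail (two-sided by flag), the
sample odds ratio from the 2×2 table, and BH adjustment across
annotations; it is exact against full enumeration for universes up to 30.
The universe must be supplied explicitly — the default in the pipelines is
all genes surviving expression filtering — because silently mismatched
universes are the classic failure mode of enrichment analyses.
`percent_overlap()` is the worked-example helper (248 of 277 reports 90%);
`random_subset()` provides the seeded random baselines (the seed is
mandatory and logged, since the original analyses do not state one), and
`geneset_shift()` compares target-set fold-changes against such baselines
with ANOVA plus pairwise rank-sum tests.

## The synthetic-data generator

The generator defines the study conditions the tests and acceptance checks
run under; its defaults were fixed once, up front.

**ChIP**: a 50 Mb single-chromosome target genome in 5000 × 10 kb bins,
sequencing depth $10^6$ reads per sample, 3 replicates per condition,
spike fraction 0.05 of the control IP's chromatin mass (the bench protocol
reports final spike concentrations of roughly 1–5%). Per sample, reads are
split binomially between target and spike by true mass (treated target mass
scaled by `r_global`; spike constant), then distributed multinomially over
bins along the signal profile — background 1×, implanted domains at their
multipliers, with a shared 5% log-normal bin-to-bin roughness so that
IP/input ratios stay clean while neither profile is perfectly flat
(`input_uniformity` switches the roughness off). Reads per sample sum to
depth exactly. A closed-form expectation calculator (`chip_expectation()`)
provides the oracle that Monte-Carlo averages are tested against.

**RNA**: 2000 genes with log-normal per-cell abundances drawn once and
shared by both conditions, 92 ERCC-style spike species at 5% of the control
gene mass, depth $10^6$, 3+3 samples, NB overdispersion 0.05. Treated
abundances are multiplied by `g_global` and per-gene differential effects;
spikes are never touched, and batch offsets (per gene × batch, log-normal)
apply to gene rows only — the spikes are added after lysis in the real
protocol, so batch structure must not reach them. Libraries are drawn by a
Dirichlet-multinomial scheme (gamma-perturbed proportions, then a
multinomial of exactly `depth` reads): this reconciles negative-binomial
marginal noise with exact conservation of the library size, and reduces to
a pure multinomial at dispersion 0. Seeding is hierarchical: one master
seed, fixed-offset child streams per sample, so samples are independent
but jointly reproducible, and seeded helpers restore the caller's RNG
state.

What the generator does **not** emulate: mappability and sequence
composition, duplicate reads, fragment-length effects, gene length bias,
correlated gene programs, and dispersion trends that vary with expression.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated model — not that any particular
biological dataset will meet that model's assumptions.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to 1-based closed happens only at the GenomicRanges boundary.
* Poisson tail tests use $P(X \ge \lceil x \rceil)$ so scaled non-integer
  counts are handled conservatively.
* Zero-spike samples, all-zero inputs, empty enrichment distributions,
  batches with one sample, and annotation sets disjoint from the universe
  all raise typed errors (or flagged degenerate rows) rather than
  propagating NaNs; zero-input bins and zero-control repeat elements are
  excluded *with a tally* so losses are visible.
* The EB iterations in `batch_adjust()` stop at a relative change of
  1e-4, matching the reference implementation they are tested against.
* Problem sizes in the tests and acceptance script — 5000 bins at depth
  $10^6$, 2000 genes, 100-seed calibration loops — are the package's
  chosen desk-scale study conditions; each completes in seconds.

## Known limitations

* The broad-domain caller is a calibrated simplification; it does not
  emulate the island-scoring statistics of SICER-family callers, only the
  stated post-processing.
* The NB Wald test is moment-based; at very low counts its p-values are
  approximate (the tests bound its null behaviour rather than assert
  exactness).
* `aggregate_signal_matrix()` operates at the bin resolution of its input
  signal; it does not re-bin below that resolution.
* Normalization factors assume spike material was added proportionally to
  cell input; violations of that bench-side assumption are invisible to
  the statistics downstream.
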