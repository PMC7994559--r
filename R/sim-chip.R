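#' Parameters for a spike-in ChIP-seq simulation
#'
#' Describes a two-condition (control vs treated) immunoprecipitation
#' experiment in which the treated condition's true per-cell signal mass is
#' globally scaled by `r_global`, while a constant amount of exogenous
#' (spike) chromatin is present in every IP.  Sequencing is at a fixed total
#' depth, so a global gain or loss of signal is visible only through the
#' target:spike read split - the measurement the spike-in normalization
#' factor exploits.
#'
#' @param n_bins number of uniform bins tiling the target genome.
#' @param bin_width bin width in bases (default 10 kb).
#' @param n_spike_bins bins tiling the spike genome (bookkeeping only;
#'   spike reads are summarised per sample).
#' @param domain_spec data frame with columns `start_bin`, `n_bins`,
#'   `multiplier`: broad domains whose bins carry `multiplier`-fold
#'   enrichment over the 1x background.
#' @param r_global ratio of treated to control true per-cell signal mass.
#' @param spike_fraction fraction of IP chromatin mass from the spike genome
#'   in the control condition; must lie in (0, 1).
#' @param depth total sequenced reads per sample (target + spike sum to this
#'   exactly).
#' @param n_replicates biological replicates per condition.
#' @param input_uniformity if `TRUE` the input profile is exactly uniform;
#'   otherwise it carries 5% bin-to-bin log-normal roughness.
#' @param seed master seed; per-sample child streams are derived from it.
#' @return a `chip_sim_params` list.
#' @export
chip_sim_params <- function(n_bins = 5000, bin_width = 10000,
                            n_spike_bins = 1000,
                            domain_spec = NULL,
                            r_global = 1, spike_fraction = 0.05,
                            depth = 1e6, n_replicates = 3,
                            input_uniformity = FALSE, seed = 1) {
  assert_that(spike_fraction > 0 && spike_fraction < 1,
              "spike_fraction must lie in (0, 1)")
  assert_that(r_global > 0, "r_global must be positive")
  assert_that(depth > 0, "depth must be positive")
  if (is.null(domain_spec)) {
    domain_spec <- data.frame(start_bin = integer(), n_bins = integer(),
                              multiplier = numeric())
  }
  domain_spec <- as.data.frame(domain_spec)
  if (nrow(domain_spec) > 0) {
    assert_that(all(domain_spec$start_bin >= 1) &&
                  all(domain_spec$start_bin + domain_spec$n_bins - 1 <= n_bins),
                "domain_spec exceeds the genome")
    assert_that(all(domain_spec$multiplier > 0),
                "domain multipliers must be positive")
  }
  structure(list(n_bins = n_bins, bin_width = bin_width,
                 n_spike_bins = n_spike_bins, domain_spec = domain_spec,
                 r_global = r_global, spike_fraction = spike_fraction,
                 depth = depth, n_replicates = n_replicates,
                 input_uniformity = input_uniformity,
                 seed = as.integer(seed)),
            class = "chip_sim_params")
}

# Deterministic per-bin profiles given the params (shared roughness is
# applied to both IP signal and input so that their ratio is clean).
chip_profiles <- function(params) {
  n <- params$n_bins
  signal <- rep(1, n)
  ds <- params$domain_spec
  if (nrow(ds) > 0) {
    for (i in seq_len(nrow(ds))) {
      idx <- seq(ds$start_bin[i], length.out = ds$n_bins[i])
      signal[idx] <- signal[idx] * ds$multiplier[i]
    }
  }
  rough <- if (params$input_uniformity) rep(1, n) else
    with_seed(child_seed(params$seed, 0L), rlnorm(n, 0, 0.05))
  list(signal = signal * rough / sum(signal * rough),
       input = rough / sum(rough))
}

chip_sample_sheet <- function(params) {
  grid <- expand.grid(role = c("IP", "input"),
                      replicate = seq_len(params$n_replicates),
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_rep%d_%s", grid$condition, grid$replicate,
                         grid$role)
  grid[, c("sample", "role", "condition", "replicate")]
}

#' Closed-form expectations for a ChIP simulation
#'
#' Computes, without any sampling, the expected target/spike read split per
#' sample and the expected per-bin target counts, conditional on the
#' (seed-determined) bin profiles.  This is the oracle Monte-Carlo averages
#' must converge to.
#'
#' @param params a [chip_sim_params()].
#' @return list with `samples` (expected split per sample) and
#'   `expected_bins` (bins x samples matrix of expected counts).
#' @export
chip_expectation <- function(params) {
  prof <- chip_profiles(params)
  sheet <- chip_sample_sheet(params)
  sf <- params$spike_fraction
  e_target <- e_spike <- numeric(nrow(sheet))
  ebins <- matrix(0, params$n_bins, nrow(sheet),
                  dimnames = list(NULL, sheet$sample))
  for (i in seq_len(nrow(sheet))) {
    r <- if (sheet$condition[i] == "treated") params$r_global else 1
    if (sheet$role[i] == "IP") {
      p_spike <- sf / (sf + r * (1 - sf))
      p_bins <- prof$signal
    } else {
      p_spike <- sf
      p_bins <- prof$input
    }
    e_spike[i] <- params$depth * p_spike
    e_target[i] <- params$depth * (1 - p_spike)
    ebins[, i] <- e_target[i] * p_bins
  }
  list(samples = cbind(sheet, expected_target = e_target,
                       expected_spike = e_spike),
       expected_bins = ebins, profiles = prof)
}

#' Simulate a spike-in ChIP-seq experiment
#'
#' Per sample, `depth` reads are split between the target and spike genomes
#' binomially according to their true chromatin-mass shares (the treated
#' condition's target mass is scaled by `r_global`; the spike mass is
#' constant), and the target reads are then distributed over genomic bins
#' multinomially along the signal (IP) or near-uniform (input) profile.
#' Reads per sample sum to `depth` exactly, and the whole draw is
#' reproducible from the master seed.
#'
#' @param params a [chip_sim_params()].
#' @return list with components
#'   `species_counts` (data frame: sample, role, condition, replicate,
#'   target_reads, spike_reads),
#'   `ip_bins` / `input_bins` ([bin_matrix()] of raw target-genome counts),
#'   `genome` (the target [genome_index()]), and `truth` (a `sim_truth`
#'   manifest with the parameters, profiles and expectations).
#' @export
simulate_chip_experiment <- function(params) {
  assert_that(inherits(params, "chip_sim_params"),
              "params must come from chip_sim_params()")
  expect <- chip_expectation(params)
  sheet <- expect$samples
  prof <- expect$profiles
  counts <- matrix(0, params$n_bins, nrow(sheet),
                   dimnames = list(NULL, sheet$sample))
  target_reads <- spike_reads <- integer(nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    p_spike <- sheet$expected_spike[i] / params$depth
    p_bins <- if (sheet$role[i] == "IP") prof$signal else prof$input
    drawn <- with_seed(child_seed(params$seed, i), {
      s <- rbinom(1, params$depth, p_spike)
      b <- rmultinom(1, params$depth - s, p_bins)[, 1]
      list(spike = s, bins = b)
    })
    spike_reads[i] <- drawn$spike
    target_reads[i] <- params$depth - drawn$spike
    counts[, i] <- drawn$bins
  }
  genome <- genome_index(setNames(params$n_bins * params$bin_width, "chrT"))
  bins <- bin_genome(genome, params$bin_width)
  species <- data.frame(sheet[, c("sample", "role", "condition", "replicate")],
                        target_reads = target_reads,
                        spike_reads = spike_reads)
  is_ip <- sheet$role == "IP"
  truth <- structure(list(kind = "chip", params = params,
                          profiles = prof,
                          expected = expect$samples,
                          expected_bins = expect$expected_bins,
                          seed = params$seed),
                     class = "sim_truth")
  ss_log("simulate_chip_experiment: %d bins x %d samples, depth %g, r_global %g, seed %d",
         params$n_bins, nrow(sheet), params$depth, params$r_global,
         params$seed)
  list(species_counts = species,
       ip_bins = bin_matrix(bins, counts[, is_ip, drop = FALSE]),
       input_bins = bin_matrix(bins, counts[, !is_ip, drop = FALSE]),
       genome = genome,
       truth = truth)
}

#' Serialize / restore a simulation manifest
#'
#' `sim_truth` objects are written as structured JSON text so a simulation's
#' expectations can be recomputed exactly.
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path` invisibly; `read_sim_truth()` returns the parsed list.
#' @export
write_sim_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
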