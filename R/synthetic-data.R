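#' Configuration for a synthetic SNP-array study panel
#'
#' Describes an emulated array panel: a generating demographic scenario
#' with point parameter values, diploid counts per population, the number
#' of loci, two independent layers of missing calls (one attributed to SNP
#' quality, one to sample quality), clonal duplicate samples with genotype
#' error, and the ascertainment minor-allele-frequency floor.
#'
#' @param scenario a [scenario()].
#' @param params named numeric vector of parameter values for `scenario`.
#' @param diploid_counts named integer vector of diploids per population.
#' @param n_loci SNP loci before filtering.
#' @param snp_missing_rate,sample_missing_rate per-cell missing-call
#'   probabilities for the two layers (each in [0, 1)).
#' @param n_clones number of duplicated (clonal) profiles to append.
#' @param clone_error_rate per-locus genotype-error probability in a clone.
#' @param maf ascertainment minor allele frequency for simulated loci.
#' @param seed integer seed.
#' @return A validated config list of class `study_config`.
#' @export
study_config <- function(scenario, params, diploid_counts, n_loci,
                         snp_missing_rate = 0, sample_missing_rate = 0,
                         n_clones = 0, clone_error_rate = 0.01,
                         maf = 0.05, seed = 1) {
  stopifnot(
    snp_missing_rate >= 0, snp_missing_rate < 1,
    sample_missing_rate >= 0, sample_missing_rate < 1,
    clone_error_rate >= 0, clone_error_rate < 1,
    n_clones >= 0, n_loci >= 1, all(diploid_counts >= 1)
  )
  structure(
    list(scenario = scenario, params = params,
         diploid_counts = diploid_counts, n_loci = n_loci,
         snp_missing_rate = snp_missing_rate,
         sample_missing_rate = sample_missing_rate,
         n_clones = n_clones, clone_error_rate = clone_error_rate,
         maf = maf, seed = seed),
    class = "study_config"
  )
}

#' Generate a synthetic study panel with known ground truth
#'
#' Simulates genotypes under the configured scenario, injects missing calls
#' by independent Bernoulli draws at the two configured rates, and appends
#' clone samples copied from randomly chosen originals with independent
#' per-locus genotype error (a symmetric flip to one of the other two
#' dosage values). The manifest records everything a test needs to verify
#' recovery: the true scenario and parameters, the clone pairs, and the
#' injected missing-cell count.
#'
#' @param config a [study_config()].
#' @return list(`genotypes` (a [genotype_matrix()]), `manifest`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  g <- simulate_dataset(config$scenario, config$params,
                        config$diploid_counts, config$n_loci,
                        min_maf = config$maf)
  d <- g$dosages
  n <- nrow(d); m <- ncol(d)

  clone_pairs <- NULL
  if (config$n_clones > 0) {
    originals <- sample.int(n, config$n_clones, replace = FALSE)
    clones <- d[originals, , drop = FALSE]
    err <- matrix(stats::runif(config$n_clones * m) < config$clone_error_rate,
                  config$n_clones, m)
    if (any(err)) {
      # symmetric flip to a different dosage value
      flip <- function(x) (x + sample(1:2, length(x), replace = TRUE)) %% 3L
      clones[err] <- flip(clones[err])
    }
    clone_ids <- paste0(g$sample_ids[originals], "_clone",
                        seq_len(config$n_clones))
    clone_pairs <- data.frame(original = g$sample_ids[originals],
                              clone = clone_ids, stringsAsFactors = FALSE)
    d <- rbind(d, clones)
    g <- genotype_matrix(d, c(g$sample_ids, clone_ids),
                         c(g$pop_labels, g$pop_labels[originals]), g$loci)
    n <- nrow(d)
  }

  miss <- matrix(stats::runif(n * m) < config$snp_missing_rate, n, m) |
    matrix(stats::runif(n * m) < config$sample_missing_rate, n, m)
  d <- g$dosages
  d[miss] <- NA_integer_
  g <- genotype_matrix(d, g$sample_ids, g$pop_labels, g$loci)

  manifest <- list(
    scenario_id = config$scenario$id,
    params = as.list(config$params),
    diploid_counts = as.list(config$diploid_counts),
    n_loci = config$n_loci,
    clone_pairs = clone_pairs,
    n_missing_cells = sum(miss),
    seed = config$seed
  )
  list(genotypes = g, manifest = manifest)
}
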