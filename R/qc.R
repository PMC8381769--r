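#' SNP-level quality-control filter
#'
#' Removes loci whose missing-call rate exceeds `max_na_rate` or whose minor
#' allele frequency (computed from non-missing dosages) falls below
#' `min_maf`. The defaults reproduce the stringent array-panel filter used
#' throughout the pipeline: NA rate <= 1%, MAF >= 5%.
#'
#' @param g a [genotype_matrix()].
#' @param max_na_rate maximum tolerated per-locus missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @return A list with the filtered `genotype_matrix` and a `qc_report`.
#' @export
filter_snps <- function(g, max_na_rate = 0.01, min_maf = 0.05) {
  stopifnot(max_na_rate >= 0, max_na_rate < 1, min_maf >= 0, min_maf <= 0.5)
  d <- g$dosages
  na_rate <- colMeans(is.na(d))
  nn <- 2 * colSums(!is.na(d))
  p <- ifelse(nn > 0, colSums(d, na.rm = TRUE) / nn, 0)
  maf <- pmin(p, 1 - p)
  fail_na <- na_rate > max_na_rate
  fail_maf <- !fail_na & maf < min_maf
  keep <- which(!fail_na & !fail_maf)
  if (length(keep) == 0) stop("all loci removed by the SNP filter")
  out <- subset_genotypes(g, loci = keep)
  report <- qc_report(
    n_snps_removed_narate = sum(fail_na),
    n_snps_removed_maf = sum(fail_maf),
    kept_sample_ids = g$sample_ids,
    kept_locus_indices = keep,
    input_dim = dim(g$dosages)
  )
  list(genotypes = out, report = report)
}

#' Sample-level quality-control filter
#'
#' Removes samples whose missing-call rate across loci exceeds
#' `max_na_rate` (default 5%).
#'
#' @inheritParams filter_snps
#' @param max_na_rate maximum tolerated per-sample missing fraction.
#' @return A list with the filtered `genotype_matrix` and a `qc_report`.
#' @export
filter_samples <- function(g, max_na_rate = 0.05) {
  stopifnot(max_na_rate >= 0)
  na_rate <- rowMeans(is.na(g$dosages))
  keep <- which(na_rate <= max_na_rate)
  if (length(keep) == 0) stop("all samples removed by the sample filter")
  out <- subset_genotypes(g, samples = keep)
  report <- qc_report(
    n_samples_removed_narate = n_samples(g) - length(keep),
    kept_sample_ids = g$sample_ids[keep],
    kept_locus_indices = seq_len(n_loci(g)),
    input_dim = dim(g$dosages)
  )
  list(genotypes = out, report = report)
}

qc_report <- function(n_snps_removed_narate = 0L, n_snps_removed_maf = 0L,
                      n_samples_removed_narate = 0L, duplicate_pairs = NULL,
                      kept_sample_ids = character(), kept_locus_indices = integer(),
                      input_dim = c(0L, 0L)) {
  structure(
    list(
      n_snps_removed_narate = as.integer(n_snps_removed_narate),
      n_snps_removed_maf = as.integer(n_snps_removed_maf),
      n_samples_removed_narate = as.integer(n_samples_removed_narate),
      duplicate_pairs = duplicate_pairs,
      kept_sample_ids = kept_sample_ids,
      kept_locus_indices = kept_locus_indices,
      input_dim = as.integer(input_dim)
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  SNPs removed (NA rate): ", x$n_snps_removed_narate, "\n",
      "  SNPs removed (MAF):     ", x$n_snps_removed_maf, "\n",
      "  samples removed:        ", x$n_samples_removed_narate, "\n",
      "  duplicate pairs:        ",
      if (is.null(x$duplicate_pairs)) 0 else nrow(x$duplicate_pairs), "\n",
      sep = "")
  invisible(x)
}

#' Detect duplicated (clonal) genotype profiles
#'
#' Computes the pairwise mismatch fraction over loci called in both samples
#' and flags pairs below `mismatch_cutoff` (default 20%) as duplicates —
#' the signature of clonally propagated material genotyped more than once.
#' Pairs with no shared called locus are skipped with a warning.
#'
#' @inheritParams filter_snps
#' @param mismatch_cutoff pairs with mismatch fraction strictly below this
#'   are flagged.
#' @return A data frame with columns `sample_i`, `sample_j`,
#'   `mismatch_fraction`.
#' @export
find_duplicates <- function(g, mismatch_cutoff = 0.20) {
  d <- g$dosages
  n <- nrow(d)
  out <- list()
  skipped <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- !is.na(d[i, ]) & !is.na(d[j, ])
        ns <- sum(shared)
        if (ns == 0) { skipped <- skipped + 1L; next }
        mm <- sum(d[i, shared] != d[j, shared]) / ns
        if (mm < mismatch_cutoff)
          out[[length(out) + 1L]] <- data.frame(
            sample_i = g$sample_ids[i], sample_j = g$sample_ids[j],
            mismatch_fraction = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " pair(s) with no shared called locus skipped")
  if (length(out) == 0)
    return(data.frame(sample_i = character(), sample_j = character(),
                      mismatch_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Remove duplicated profiles
#'
#' Treats flagged duplicate pairs as edges of a graph and keeps, from each
#' connected component, the sample that appears first in input order.
#'
#' @inheritParams filter_snps
#' @param pairs data frame as returned by [find_duplicates()].
#' @return A `genotype_matrix` without the later members of each component.
#' @export
deduplicate <- function(g, pairs) {
  if (nrow(pairs) == 0) return(g)
  # union-find over sample indices
  parent <- seq_len(n_samples(g))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$sample_i[k], g$sample_ids)
    j <- match(pairs$sample_j[k], g$sample_ids)
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_along(parent), find, 1L)
  keep <- which(!duplicated(roots))
  subset_genotypes(g, samples = keep)
}

#' Full panel QC in the standard order
#'
#' SNP filter, then sample filter, then duplicate removal — the order used
#' for array panels where locus quality is assessed on the full sample.
#'
#' @inheritParams filter_snps
#' @param max_snp_na,min_maf thresholds for [filter_snps()].
#' @param max_sample_na threshold for [filter_samples()].
#' @param dup_cutoff threshold for [find_duplicates()].
#' @return list(genotypes, report) where `report` aggregates all stages.
#' @export
qc_pipeline <- function(g, max_snp_na = 0.01, min_maf = 0.05,
                        max_sample_na = 0.05, dup_cutoff = 0.20) {
  s1 <- filter_snps(g, max_snp_na, min_maf)
  s2 <- filter_samples(s1$genotypes, max_sample_na)
  dups <- find_duplicates(s2$genotypes, dup_cutoff)
  g3 <- deduplicate(s2$genotypes, dups)
  report <- qc_report(
    n_snps_removed_narate = s1$report$n_snps_removed_narate,
    n_snps_removed_maf = s1$report$n_snps_removed_maf,
    n_samples_removed_narate = s2$report$n_samples_removed_narate,
    duplicate_pairs = dups,
    kept_sample_ids = g3$sample_ids,
    kept_locus_indices = s1$report$kept_locus_indices,
    input_dim = dim(g$dosages)
  )
  list(genotypes = g3, report = report)
}

#' Variance-inflation-factor LD pruning
#'
#' Sliding-window pruning of loci in strong linkage disequilibrium: within
#' each window of `window_snps` loci, the locus with the highest variance
#' inflation factor (VIF = 1/(1 - R^2) from regressing its dosage on the
#' other kept loci in the window) is removed until all VIFs are below
#' `vif_threshold`; the window then advances by `step_snps` loci. A locus
#' removed in any window stays removed. Missing dosages are mean-imputed for
#' the regressions only. The default 50/5/2 triple is the conventional
#' independence-pruning setting.
#'
#' @inheritParams filter_snps
#' @param window_snps window width in loci (>= 2).
#' @param step_snps window step in loci.
#' @param vif_threshold loci with VIF >= this are pruned.
#' @return Integer vector of kept locus indices.
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 5, vif_threshold = 2) {
  if (window_snps < 2) stop("`window_snps` must be >= 2")
  stopifnot(vif_threshold > 1, step_snps >= 1)
  m <- n_loci(g)
  x <- g$dosages
  storage.mode(x) <- "double"
  for (j in seq_len(m)) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  removed <- rep(FALSE, m)
  start <- 1
  repeat {
    end <- min(start + window_snps - 1, m)
    idx <- setdiff(seq(start, end), which(removed))
    repeat {
      if (length(idx) < 2) break
      vifs <- vapply(seq_along(idx), function(k) {
        y <- x[, idx[k]]
        X <- x[, idx[-k], drop = FALSE]
        if (stats::var(y) == 0) return(1)
        fit <- stats::lm.fit(cbind(1, X), y)
        r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
        r2 <- min(r2, 1 - 1e-12)
        1 / (1 - r2)
      }, 1.0)
      if (max(vifs) < vif_threshold) break
      # highest VIF first; ties broken towards the later-indexed locus so a
      # perfect copy removes the copy, not the original
      worst <- which(vifs == max(vifs))
      drop_k <- worst[length(worst)]
      removed[idx[drop_k]] <- TRUE
      idx <- idx[-drop_k]
    }
    if (end >= m) break
    start <- start + step_snps
  }
  which(!removed)
}

#' Greedy allele-coverage core selection
#'
#' Selects a core subset of a population that maximizes covered
#' (locus, allele) pairs by greedy set cover: start with the sample covering
#' the most alleles, then repeatedly add the sample contributing the most
#' uncovered alleles; ties are broken by input order.
#'
#' @inheritParams filter_snps
#' @param pop population to draw the core from.
#' @param size number of samples to select (1..population size).
#' @return Character vector of selected sample ids (length `size`).
#' @export
select_core <- function(g, pop, size) {
  if (size <= 0) stop("`size` must be positive")
  rows <- which(g$pop_labels == pop)
  if (length(rows) == 0) stop("population not present: ", pop)
  if (size > length(rows)) stop("`size` exceeds population sample count")
  d <- g$dosages[rows, , drop = FALSE]
  m <- ncol(d)
  # columns of the coverage matrix: (locus, ref) then (locus, alt)
  cov_ref <- !is.na(d) & d <= 1   # carries reference allele
  cov_alt <- !is.na(d) & d >= 1   # carries alternate allele
  cover <- cbind(cov_ref, cov_alt)
  chosen <- integer(0)
  covered <- rep(FALSE, 2 * m)
  remaining <- seq_along(rows)
  for (step in seq_len(size)) {
    gains <- vapply(remaining, function(r) sum(cover[r, ] & !covered), 0L)
    best <- remaining[which.max(gains)]   # which.max takes the first tie
    chosen <- c(chosen, best)
    covered <- covered | cover[best, ]
    remaining <- setdiff(remaining, best)
  }
  g$sample_ids[rows[chosen]]
}

#' Fraction of observed (locus, allele) pairs covered by a sample subset
#'
#' @inheritParams select_core
#' @param sample_ids samples forming the subset.
#' @return A fraction in [0, 1].
#' @export
allele_coverage <- function(g, sample_ids) {
  rows <- match(sample_ids, g$sample_ids)
  if (anyNA(rows)) stop("unknown sample id")
  d_all <- g$dosages
  d <- d_all[rows, , drop = FALSE]
  obs <- c(colSums(!is.na(d_all) & d_all <= 1) > 0,
           colSums(!is.na(d_all) & d_all >= 1) > 0)
  hit <- c(colSums(!is.na(d) & d <= 1) > 0,
           colSums(!is.na(d) & d >= 1) > 0)
  sum(hit & obs) / sum(obs)
}
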