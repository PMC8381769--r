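#' @useDynLib vineflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Encode a scenario + concrete parameter values for the C++ engine:
# populations as 0-based indices, events sorted by concrete time (stable for
# ties, preserving the listed order).
scenario_encode <- function(s, params) {
  pops <- s$pops
  missing <- setdiff(scenario_params(s), names(params))
  if (length(missing))
    stop("parameter value(s) missing: ", paste(missing, collapse = ", "))
  pop_idx <- function(x) match(x, pops) - 1L
  ev <- s$events
  times <- unname(params[ev$time_param])
  ord <- order(times)
  ev <- ev[ord, , drop = FALSE]
  times <- times[ord]
  list(
    ne = unname(params[s$ne_params[pops]]),
    ev_time = as.numeric(times),
    ev_type = as.integer(ev$type == "admixture"),
    ev_derived = pop_idx(ev$derived),
    ev_s1 = pop_idx(ev$source1),
    ev_s2 = ifelse(is.na(ev$source2), 0L, pop_idx(ev$source2)),
    ev_prop = as.numeric(ifelse(is.na(ev$prop_param), 0,
                                params[ev$prop_param]))
  )
}

#' Simulate one genealogy under a scenario
#'
#' Continuous-time structured coalescent: within a population of diploid
#' size Ne any lineage pair coalesces at rate 1/(2 Ne) per generation; at a
#' divergence event all lineages of the derived population move to the
#' source; at an admixture event each lineage moves independently to source
#' A with the admixture proportion, else to source B. The process runs in
#' the root population until a single lineage remains.
#'
#' @param s a [scenario()].
#' @param params named numeric vector (e.g. from [draw_parameters()]).
#' @param sample_sizes named integer vector: gene copies per sampled
#'   population.
#' @param seed optional integer seed.
#' @return An object of class `genealogy`: `parent` (1-based, `NA` at the
#'   root), `time` (node times in generations, tips at 0), `tip_pop`
#'   (population per tip) and `n_tips`.
#' @export
simulate_genealogy <- function(s, params, sample_sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(sample_sizes) %in% s$pops), all(sample_sizes >= 1))
  enc <- scenario_encode(s, params)
  tip_pop <- rep(match(names(sample_sizes), s$pops) - 1L, sample_sizes)
  res <- cpp_sim_genealogy(tip_pop, enc$ne, enc$ev_time, enc$ev_type,
                           enc$ev_derived, enc$ev_s1, enc$ev_s2, enc$ev_prop)
  structure(
    list(parent = res$parent, time = res$time, n_tips = res$n_tips,
         tip_pop = s$pops[tip_pop + 1L]),
    class = "genealogy"
  )
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n_tips, " tips, TMRCA = ",
      format(max(x$time), digits = 5), " generations\n", sep = "")
  invisible(x)
}

#' Time to the most recent common ancestor of a genealogy
#' @param gen a `genealogy`.
#' @return TMRCA in generations.
#' @export
tmrca <- function(gen) max(gen$time)

#' Drop a single SNP mutation onto a genealogy
#'
#' One branch is chosen with probability proportional to its length among
#' all branches strictly below the root; tips descending from it carry the
#' derived allele, so the returned column is always polymorphic in the
#' pooled sample. If the minor-allele count falls below `min_minor_count`
#' the locus is redrawn: a fresh genealogy is requested through
#' `regenerate` when supplied (the behaviour used by [simulate_dataset()]),
#' otherwise the mutation is re-placed on the same genealogy.
#'
#' @param gen a `genealogy` with >= 2 tips.
#' @param min_minor_count minimum pooled minor-allele count.
#' @param regenerate optional zero-argument function returning a fresh
#'   `genealogy` for a full locus redraw.
#' @return Integer vector of 0/1 alleles, one per gene copy.
#' @export
drop_snp_mutation <- function(gen, min_minor_count = 1, regenerate = NULL) {
  if (gen$n_tips < 2) stop("genealogy must have at least 2 tips")
  for (try in seq_len(100000)) {
    n_nodes <- length(gen$parent)
    n <- gen$n_tips
    len <- rep(0, n_nodes)
    below <- !is.na(gen$parent)
    len[below] <- gen$time[gen$parent[below]] - gen$time[below]
    node <- sample.int(n_nodes, 1, prob = len)
    carriers <- rep(FALSE, n_nodes)
    carriers[node] <- TRUE
    ord <- order(gen$time, decreasing = TRUE)  # parents before children
    for (v in ord) {
      p <- gen$parent[v]
      if (!is.na(p) && carriers[p] && v != node) carriers[v] <- carriers[p]
    }
    # propagate top-down: repeat passes until fixpoint is unnecessary since
    # parents always have later times than children in a coalescent tree
    hap <- as.integer(carriers[seq_len(n)])
    minor <- min(sum(hap), n - sum(hap))
    if (minor >= min_minor_count) return(hap)
    if (!is.null(regenerate)) gen <- regenerate()
  }
  stop("could not satisfy the minor-allele condition")
}

#' Simulate a SNP dataset under a scenario
#'
#' `n_loci` independent biallelic loci for the requested diploid samples:
#' per locus a fresh genealogy plus a single mutation, conditioned on a
#' pooled minor allele frequency of at least `min_maf` (the SNP-array
#' ascertainment mirror of the observed-panel filter; set it to 0 for plain
#' polymorphism conditioning). Gene copies are paired into diploids within
#' population. Loci get positions drawn uniformly over a synthetic map so
#' downstream code requiring coordinates runs unchanged; the loci are
#' unlinked regardless of assigned position.
#'
#' @inheritParams simulate_genealogy
#' @param diploid_counts named integer vector: diploid individuals per
#'   sampled population.
#' @param n_loci number of SNP loci.
#' @param min_maf minimum pooled minor allele frequency per locus.
#' @param n_chrom,chrom_bp synthetic map layout (chromosome count and
#'   length in base pairs).
#' @return A [genotype_matrix()] with no missing calls.
#' @export
simulate_dataset <- function(s, params, diploid_counts, n_loci,
                             seed = NULL, min_maf = 0.05,
                             n_chrom = 19, chrom_bp = 2e7) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_loci >= 1, all(diploid_counts >= 1))
  enc <- scenario_encode(s, params)
  pops <- names(diploid_counts)
  tip_pop <- rep(match(pops, s$pops) - 1L, 2L * diploid_counts)
  n_copies <- length(tip_pop)
  min_minor <- max(1L, as.integer(ceiling(min_maf * n_copies)))
  dos <- cpp_sim_dataset(tip_pop, enc$ne, enc$ev_time, enc$ev_type,
                         enc$ev_derived, enc$ev_s1, enc$ev_s2, enc$ev_prop,
                         as.integer(n_loci), min_minor)
  chrom <- sample.int(n_chrom, n_loci, replace = TRUE)
  pos <- sample.int(chrom_bp, n_loci, replace = TRUE)
  loci <- data.frame(chrom = sprintf("chr%02d", chrom), pos = pos,
                     ref = "A", alt = "B", stringsAsFactors = FALSE)
  ids <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s_%03d", pops[k], seq_len(diploid_counts[k]))))
  genotype_matrix(dos, ids, rep(pops, diploid_counts), loci)
}
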