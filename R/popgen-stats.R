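#' Unbiased gene diversity (expected heterozygosity)
#'
#' Per locus, H = n(1 - p^2 - q^2)/(n - 1) with n observed gene copies and p
#' the alternate-allele frequency; the value returned is the mean over loci
#' with at least two gene copies. Loci with no calls in the population are
#' skipped.
#'
#' @param g a [genotype_matrix()].
#' @param pop population name.
#' @return Mean unbiased gene diversity across usable loci.
#' @export
gene_diversity <- function(g, pop) {
  ft <- allele_freq_table(g, pop)
  mean(gene_diversity_from_freqs(ft$p[1, ], ft$n[1, ]))
}

gene_diversity_from_freqs <- function(p, n) {
  usable <- n >= 2
  if (!any(usable)) stop("no usable loci for gene diversity")
  p <- p[usable]; n <- n[usable]
  n * (1 - p^2 - (1 - p)^2) / (n - 1)
}

#' Pairwise Fst (Weir and Cockerham 1984)
#'
#' Variance-components estimator of the fixation index between two
#' populations: per-locus components a (among populations), b (among
#' individuals within populations) and c (within individuals), combined as
#' sum(a) / sum(a + b + c) over loci. Loci monomorphic across both
#' populations contribute nothing; the estimate may be slightly negative.
#'
#' @inheritParams gene_diversity
#' @param popA,popB population names.
#' @return The multi-locus Fst estimate.
#' @export
pairwise_fst <- function(g, popA, popB) {
  rowsA <- g$pop_labels == popA
  rowsB <- g$pop_labels == popB
  if (!any(rowsA) || !any(rowsB)) stop("population not present")
  comp <- wc_fst_components(g$dosages[rowsA, , drop = FALSE],
                            g$dosages[rowsB, , drop = FALSE])
  denom <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (!is.finite(denom) || denom == 0) stop("no usable loci for Fst")
  sum(comp$a, na.rm = TRUE) / denom
}

# Per-locus WC84 components for two populations, from dosage matrices.
# Vectorized over loci; loci with < 2 diploids called in either population or
# monomorphic across both get NA components (they drop out of the sums).
wc_fst_components <- function(dA, dB) {
  nA <- colSums(!is.na(dA)); nB <- colSums(!is.na(dB))
  pA <- ifelse(nA > 0, colSums(dA, na.rm = TRUE) / (2 * nA), NA_real_)
  pB <- ifelse(nB > 0, colSums(dB, na.rm = TRUE) / (2 * nB), NA_real_)
  hA <- ifelse(nA > 0, colSums(dA == 1, na.rm = TRUE) / nA, NA_real_)
  hB <- ifelse(nB > 0, colSums(dB == 1, na.rm = TRUE) / nB, NA_real_)
  r <- 2
  nbar <- (nA + nB) / r
  usable <- nA >= 1 & nB >= 1 & nbar > 1
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  poly <- usable & pbar > 0 & pbar < 1
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!poly] <- NA_real_; b[!poly] <- NA_real_; cc[!poly] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Nei's (1972) standard genetic distance
#'
#' D = -ln(Jxy / sqrt(Jx * Jy)) with Jx, Jy, Jxy the means over loci of the
#' within- and between-population probabilities of allelic identity. When
#' the populations share no alleles at any locus (Jxy = 0), `Inf` is
#' returned rather than an error.
#'
#' @inheritParams pairwise_fst
#' @return Nei's standard distance (possibly `Inf`).
#' @export
nei_distance <- function(g, popA, popB) {
  ft <- allele_freq_table(g, c(popA, popB))
  nei_distance_from_freqs(ft$p[1, ], ft$p[2, ], ft$n[1, ], ft$n[2, ])
}

nei_distance_from_freqs <- function(pA, pB, nA = NULL, nB = NULL) {
  usable <- is.finite(pA) & is.finite(pB)
  if (!is.null(nA)) usable <- usable & nA > 0 & nB > 0
  if (!any(usable)) stop("no usable loci for Nei distance")
  pA <- pA[usable]; pB <- pB[usable]
  jx <- mean(pA^2 + (1 - pA)^2)
  jy <- mean(pB^2 + (1 - pB)^2)
  jxy <- mean(pA * pB + (1 - pA) * (1 - pB))
  if (jxy <= 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

#' Pairwise Fst matrix over populations
#'
#' @inheritParams gene_diversity
#' @param pops populations (default: all, order of first appearance).
#' @return Symmetric matrix of pairwise Weir-Cockerham Fst, zero diagonal.
#' @export
fst_matrix <- function(g, pops = unique(g$pop_labels)) {
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- pairwise_fst(g, pops[i], pops[j])
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}); negative distance
#' entries (possible with the Weir-Cockerham estimator) are clamped to zero
#' before tree building.
#'
#' @param d symmetric distance matrix with zero diagonal; row/column names
#'   become the leaf labels.
#' @return An unrooted tree as a Newick string.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa for a tree")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  d[d < 0] <- 0
  tr <- ape::nj(stats::as.dist(d))
  ape::write.tree(tr)
}

#' Linkage-disequilibrium decay curve
#'
#' For every same-chromosome pair of loci at distance <= `max_dist_bp`, the
#' squared Pearson correlation of dosages over samples called at both loci
#' is assigned to a 100-kb distance bin; the curve is the per-bin mean r^2.
#' `min_maf` excludes low-frequency loci (within the chosen population)
#' before pairing.
#'
#' @inheritParams gene_diversity
#' @param pop population to restrict to (`NULL` = all samples).
#' @param max_dist_bp maximum pair distance in base pairs.
#' @param bin_bp bin width in base pairs.
#' @param min_maf minimum minor allele frequency for included loci.
#' @return An object of class `ld_decay_curve`: data frame with `bin_start`,
#'   `bin_end`, `mean_r2`, `n_pairs`, plus the threshold-crossing helper
#'   [ld_decay_distance()].
#' @export
ld_decay <- function(g, pop = NULL, max_dist_bp = 1e7, bin_bp = 1e5,
                     min_maf = 0.05) {
  if (!is.null(pop)) g <- subset_genotypes(g, samples = which(g$pop_labels == pop))
  d <- g$dosages
  nn <- 2 * colSums(!is.na(d))
  p <- ifelse(nn > 0, colSums(d, na.rm = TRUE) / nn, 0)
  maf <- pmin(p, 1 - p)
  keep <- which(maf >= min_maf & nn >= 4)
  n_bins <- ceiling(max_dist_bp / bin_bp)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  any_usable <- FALSE
  for (chr in unique(g$loci$chrom)) {
    idx <- keep[g$loci$chrom[keep] == chr]
    if (length(idx) < 2) next
    any_usable <- TRUE
    pos <- g$loci$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      for (b in seq(a + 1, length(idx))) {
        dist <- abs(pos[b] - pos[a])
        if (dist > max_dist_bp) next
        xi <- d[, idx[a]]; xj <- d[, idx[b]]
        ok <- !is.na(xi) & !is.na(xj)
        if (sum(ok) < 3) next
        if (stats::var(xi[ok]) == 0 || stats::var(xj[ok]) == 0) next
        r2 <- stats::cor(xi[ok], xj[ok])^2
        bin <- min(n_bins, floor(dist / bin_bp) + 1)
        sums[bin] <- sums[bin] + r2
        counts[bin] <- counts[bin] + 1L
      }
    }
  }
  if (!any_usable) stop("fewer than 2 usable loci on every chromosome")
  curve <- data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_bp,
    bin_end = seq_len(n_bins) * bin_bp,
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts
  )
  structure(list(curve = curve, bin_bp = bin_bp, max_dist_bp = max_dist_bp),
            class = "ld_decay_curve")
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  nz <- x$curve[x$curve$n_pairs > 0, ]
  cat("<ld_decay_curve> ", nrow(nz), " non-empty ", x$bin_bp / 1000,
      "-kb bins, ", sum(x$curve$n_pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Distance at which an LD-decay curve first crosses a threshold
#'
#' Linear interpolation between consecutive non-empty bin midpoints; the
#' first downward crossing of `threshold` is reported. `NA` with a warning
#' if the curve never crosses from above.
#'
#' @param ld an `ld_decay_curve`.
#' @param threshold the r^2 level (default 0.05).
#' @return Distance in base pairs, or `NA_real_` if undefined.
#' @export
ld_decay_distance <- function(ld, threshold = 0.05) {
  cur <- ld$curve[ld$curve$n_pairs > 0, ]
  if (nrow(cur) == 0) return(NA_real_)
  mid <- (cur$bin_start + cur$bin_end) / 2
  y <- cur$mean_r2
  if (y[1] <= threshold) return(mid[1])
  for (k in seq_len(length(y) - 1)) {
    if (y[k] > threshold && y[k + 1] <= threshold) {
      f <- (y[k] - threshold) / (y[k] - y[k + 1])
      return(mid[k] + f * (mid[k + 1] - mid[k]))
    }
  }
  warning("LD curve never crosses the threshold from above")
  NA_real_
}

#' Method-of-moments identity-by-descent estimate for one pair
#'
#' Inverts the expected identity-by-state (IBS) counts given allele
#' frequencies into the probabilities (k0, k1, k2) of sharing 0/1/2 alleles
#' identical by descent, then truncates to the probability simplex.
#' pi-hat = k2 + k1/2. Allele frequencies are taken from the supplied table
#' (conventionally computed on the full sample); loci with MAF = 0 are
#' skipped.
#'
#' @inheritParams gene_diversity
#' @param i,j sample ids or indices.
#' @param freqs a single-population [allele_freq_table()] computed on the
#'   pooled sample (`NULL`: computed internally from `g`).
#' @return list(k0, k1, k2, pi_hat).
#' @export
ibd_mom <- function(g, i, j, freqs = NULL) {
  if (is.character(i)) i <- match(i, g$sample_ids)
  if (is.character(j)) j <- match(j, g$sample_ids)
  if (is.null(freqs)) {
    gg <- g; gg$pop_labels <- rep("all", n_samples(g))
    freqs <- allele_freq_table(gg, "all")
  }
  p <- freqs$p[1, ]
  di <- g$dosages[i, ]; dj <- g$dosages[j, ]
  ok <- !is.na(di) & !is.na(dj) & is.finite(p) & p > 0 & p < 1
  if (!any(ok)) stop("no usable loci for IBD")
  di <- di[ok]; dj <- dj[ok]; p <- p[ok]; q <- 1 - p
  ibs0 <- (di == 0 & dj == 2) | (di == 2 & dj == 0)
  ibs2 <- di == dj
  ibs1 <- !ibs0 & !ibs2
  N0 <- sum(ibs0); N1 <- sum(ibs1)
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1_ibd1 <- sum(2 * p * q)
  k0 <- N0 / e0_ibd0
  k1 <- (N1 - k0 * e1_ibd0) / e1_ibd1
  k2 <- 1 - k0 - k1
  # truncate to the simplex
  k <- pmax(c(k0, k1, k2), 0)
  k <- k / sum(k)
  list(k0 = k[1], k1 = k[2], k2 = k[3], pi_hat = k[3] + k[2] / 2)
}

#' Pairwise pi-hat matrix over all samples
#'
#' @inheritParams gene_diversity
#' @return Symmetric matrix of method-of-moments pi-hat values, `NA`
#'   diagonal.
#' @export
ibd_all_pairs <- function(g) {
  gg <- g; gg$pop_labels <- rep("all", n_samples(g))
  freqs <- allele_freq_table(gg, "all")
  n <- n_samples(g)
  m <- matrix(NA_real_, n, n, dimnames = list(g$sample_ids, g$sample_ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- ibd_mom(g, i, j, freqs)$pi_hat
    }
  }
  m
}

#' Log mean pi-hat per population pair
#'
#' Aggregates a pairwise pi-hat matrix to the population level: the natural
#' log of the mean pi-hat over all cross-population (or within-population,
#' on the diagonal) sample pairs. A floor of 1e-6 avoids log(0).
#'
#' @param pihat symmetric matrix from [ibd_all_pairs()].
#' @param pops population label per row of `pihat`.
#' @return Symmetric matrix of log mean pi-hat, populations as dimnames.
#' @export
group_ibd_summary <- function(pihat, pops) {
  u <- unique(pops)
  out <- matrix(NA_real_, length(u), length(u), dimnames = list(u, u))
  for (a in seq_along(u)) for (b in seq(a, length(u))) {
    ra <- which(pops == u[a]); rb <- which(pops == u[b])
    vals <- pihat[ra, rb, drop = FALSE]
    if (a == b) vals <- vals[upper.tri(vals)]
    out[a, b] <- out[b, a] <- log(max(mean(vals, na.rm = TRUE), 1e-6))
  }
  out
}

#' Classical multidimensional scaling with a fixed sign convention
#'
#' Double-centering plus eigendecomposition (via [stats::cmdscale()]); axes
#' are sign-fixed so the largest-magnitude loading of each axis is positive.
#' Negative eigenvalues (non-Euclidean input) are dropped with a warning.
#'
#' @param d distance matrix (or `dist`).
#' @param dims number of coordinates to return.
#' @return Matrix of coordinates, one row per object.
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("non-Euclidean distances: negative eigenvalues dropped")
  x <- fit$points
  for (k in seq_len(ncol(x))) {
    top <- which.max(abs(x[, k]))
    if (x[top, k] < 0) x[, k] <- -x[, k]
  }
  x
}
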