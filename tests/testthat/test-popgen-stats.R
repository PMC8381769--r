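test_that("gene diversity matches the unbiased small-sample formula", {
  # monomorphic -> 0
  g0 <- toy_gm(matrix(0L, 4, 3))
  expect_equal(gene_diversity(g0, "P1"), 0)
  # one locus, p = 0.5 with n = 4 gene copies: H = (4/3) * 0.5
  g1 <- toy_gm(matrix(c(0L, 2L), ncol = 1))
  expect_equal(gene_diversity(g1, "P1"), 4 / 3 * 0.5, tolerance = 1e-12)
  # mean over loci {0, 0.6667}
  g2 <- toy_gm(cbind(c(0L, 0L), c(0L, 2L)))
  expect_equal(gene_diversity(g2, "P1"), (0 + 2 / 3) / 2, tolerance = 1e-12)
})

test_that("Weir-Cockerham Fst hits its analytic anchors", {
  # fixed difference, no heterozygotes, equal sizes -> 1
  g <- toy_gm(rbind(matrix(2L, 5, 4), matrix(0L, 5, 4)),
              pops = rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(g, "A", "B"), 1)
  # identical all-heterozygote populations: the among-population component
  # vanishes exactly (p = 0.5, observed het = 1 makes a = 0 per locus)
  gh <- toy_gm(matrix(1L, 10, 6), pops = rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(gh, "A", "B"), 0)
  # duplicating one sample set into two "populations": the estimator has a
  # known finite-sample bias of about -1/(2 nbar - 1), not exactly zero
  set.seed(3)
  dos <- matrix(rbinom(12 * 200, 2, 0.4), 12, 200)
  gs <- toy_gm(rbind(dos, dos), pops = rep(c("A", "B"), each = 12))
  fst_dup <- pairwise_fst(gs, "A", "B")
  expect_lt(abs(fst_dup), 0.1)
  expect_lt(abs(fst_dup - (-1 / (2 * 12 - 1))), 0.03)
})

test_that("Fst and Nei agree with independent oracles on small instances", {
  # the printed toy: nA = nB = 5, pA = 0.8, pB = 0.2, 2 hets each
  dA <- matrix(c(2L, 2L, 2L, 1L, 1L), ncol = 1)  # p = 0.8, 2 hets
  dB <- matrix(c(0L, 0L, 0L, 1L, 1L), ncol = 1)  # p = 0.2, 2 hets
  g <- toy_gm(rbind(dA, dB), pops = rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(g, "A", "B"), wc84_oracle(dA, dB),
               tolerance = 1e-12)

  # random <= 10-sample sweeps against both oracles
  for (seed in 1:5) {
    g2 <- random_two_pop(5, 5, 12, seed)
    dA2 <- g2$dosages[g2$pop_labels == "A", , drop = FALSE]
    dB2 <- g2$dosages[g2$pop_labels == "B", , drop = FALSE]
    expect_equal(pairwise_fst(g2, "A", "B"), wc84_oracle(dA2, dB2),
                 tolerance = 1e-10)
    # Nei 1972 oracle: direct transcription on allele frequencies
    pA <- colMeans(dA2) / 2; pB <- colMeans(dB2) / 2
    jx <- mean(pA^2 + (1 - pA)^2); jy <- mean(pB^2 + (1 - pB)^2)
    jxy <- mean(pA * pB + (1 - pA) * (1 - pB))
    expect_equal(nei_distance(g2, "A", "B"), -log(jxy / sqrt(jx * jy)),
                 tolerance = 1e-10)
  }
})

test_that("statistics are invariant to swapping allele labels", {
  for (seed in 1:3) {
    g <- random_two_pop(5, 5, 10, seed)
    gsw <- g
    gsw$dosages <- 2L - g$dosages
    expect_equal(pairwise_fst(g, "A", "B"), pairwise_fst(gsw, "A", "B"),
                 tolerance = 1e-12)
    expect_equal(nei_distance(g, "A", "B"), nei_distance(gsw, "A", "B"),
                 tolerance = 1e-12)
    expect_equal(gene_diversity(g, "A"), gene_diversity(gsw, "A"),
                 tolerance = 1e-12)
    expect_lte(pairwise_fst(g, "A", "B"), 1)
  }
})

test_that("Nei distance anchors: identity, hand value, disjoint fixation", {
  g_same <- toy_gm(rbind(c(0L, 2L), c(2L, 0L), c(0L, 2L), c(2L, 0L)),
                   pops = rep(c("A", "B"), each = 2))
  expect_equal(nei_distance(g_same, "A", "B"), 0, tolerance = 1e-12)
  expect_equal(nei_distance(g_same, "B", "A"),
               nei_distance(g_same, "A", "B"))
  # popA p = 0.5, popB fixed: D = -ln(0.5 / sqrt(0.5))
  g1 <- toy_gm(rbind(0L, 2L, 2L, 2L) , pops = c("A", "A", "B", "B"))
  expect_equal(nei_distance(g1, "A", "B"), -log(0.5 / sqrt(0.5)),
               tolerance = 1e-4)
  # disjoint fixed alleles at every locus -> flagged infinity, no error
  g2 <- toy_gm(rbind(0L, 0L, 2L, 2L), pops = c("A", "A", "B", "B"))
  expect_identical(nei_distance(g2, "A", "B"), Inf)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths x = (dAB + dAC - dBC)/2 etc.
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- ape::read.tree(text = nj_tree(d3))
  expect_equal(sort(tr3$tip.label), c("A", "B", "C"))
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 4), tolerance = 1e-12)

  # 4-taxon additive matrix built from a known tree, inverted exactly
  true_tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):0);")
  d4 <- cophenetic(true_tree)
  tr4 <- ape::read.tree(text = nj_tree(d4))
  expect_equal(cophenetic(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)

  # permuting taxa leaves the unrooted topology unchanged
  perm <- c("C", "A", "D", "B")
  tr4p <- ape::read.tree(text = nj_tree(d4[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(tr4p))[1], 0)

  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
})

test_that("LD decay bins, exclusions and r2 match brute force", {
  set.seed(21)
  x <- rbinom(30, 2, 0.5)
  # pair A: exact copies 1 kb apart (r2 = 1); pair B engineered; far pair
  y <- ifelse(runif(30) < 0.5, x, rbinom(30, 2, 0.5))
  z <- rbinom(30, 2, 0.5)
  dos <- cbind(x, x, y, z)
  g <- toy_gm(dos, chrom = rep("chr1", 4),
              pos = c(1000L, 2000L, 250000L, 15000000L))
  ld <- ld_decay(g, max_dist_bp = 1e7, bin_bp = 1e5)
  cur <- ld$curve
  # bin 1 holds the exact-copy pair (r2 = 1)
  expect_equal(cur$mean_r2[1], 1, tolerance = 1e-12)
  # the 15-Mb locus is beyond the window: no pair with it counted
  expect_equal(sum(cur$n_pairs), 3)  # (1,2), (1,3), (2,3)
  # brute-force r2 for the pair in the 200-300 kb bin region
  r2_13 <- cor(x, y)^2
  bin_idx <- floor((250000 - 1000) / 1e5) + 1
  expect_equal(cur$mean_r2[bin_idx], mean(c(r2_13, r2_13)), tolerance = 1e-12)
  expect_true(all(cur$mean_r2[cur$n_pairs > 0] >= 0 &
                    cur$mean_r2[cur$n_pairs > 0] <= 1))
})

test_that("LD decay distance interpolates the first downward crossing", {
  curve <- data.frame(
    bin_start = c(0, 1e5, 2e5), bin_end = c(1e5, 2e5, 3e5),
    mean_r2 = c(0.30, 0.10, 0.02), n_pairs = c(10L, 10L, 10L)
  )
  ld <- structure(list(curve = curve, bin_bp = 1e5, max_dist_bp = 3e5),
                  class = "ld_decay_curve")
  # crossing of 0.05 between midpoints 150 kb (0.10) and 250 kb (0.02)
  expect_equal(ld_decay_distance(ld, 0.05), 150000 + 0.05 / 0.08 * 1e5,
               tolerance = 1e-9)
  ld$curve$mean_r2 <- c(0.3, 0.2, 0.1)
  expect_warning(res <- ld_decay_distance(ld, 0.05), "never crosses")
  expect_true(is.na(res))
})

test_that("method-of-moments IBD separates clones from unrelated pairs", {
  set.seed(31)
  m <- 1000
  p <- rep(0.5, m)
  a <- rbinom(m, 2, p)
  dos <- rbind(a, a, rbinom(m, 2, p), rbinom(m, 2, p))
  g <- toy_gm(dos)
  est <- ibd_mom(g, 1, 2)
  expect_gte(est$pi_hat, 0.95)
  expect_equal(est$k0 + est$k1 + est$k2, 1, tolerance = 1e-12)

  # unrelated pairs: mean pi-hat close to zero; the residual positive bias
  # (~0.02 at 2,000 loci) is the cost of truncating the estimate to the
  # probability simplex
  set.seed(32)
  pis <- replicate(40, {
    m2 <- 2000
    p2 <- rep(0.5, m2)
    d <- rbind(rbinom(m2, 2, p2), rbinom(m2, 2, p2))
    gg <- toy_gm(d)
    freqs <- list(p = matrix(p2, 1), n = matrix(4L, 1, m2))
    ibd_mom(gg, 1, 2, freqs)$pi_hat
  })
  expect_lt(abs(mean(pis)), 0.03)
})

test_that("IBD estimates equal an independent transcription of the inversion", {
  # oracle: scalar-by-scalar sequential method-of-moments solve
  mom_oracle <- function(di, dj, p) {
    q <- 1 - p
    n0 <- sum((di == 0 & dj == 2) | (di == 2 & dj == 0))
    n2 <- sum(di == dj)
    n1 <- length(p) - n0 - n2
    k0 <- n0 / sum(2 * p^2 * q^2)
    k1 <- (n1 - k0 * sum(4 * p^3 * q + 4 * p * q^3)) / sum(2 * p * q)
    k <- pmax(c(k0, k1, 1 - k0 - k1), 0)
    k <- k / sum(k)
    k[3] + k[2] / 2
  }
  set.seed(33)
  for (rep in 1:5) {
    m <- 300
    p <- runif(m, 0.15, 0.85)
    d <- rbind(rbinom(m, 2, p), rbinom(m, 2, p))
    g <- toy_gm(d)
    freqs <- list(p = matrix(p, 1), n = matrix(4L, 1, m))
    expect_equal(ibd_mom(g, 1, 2, freqs)$pi_hat,
                 mom_oracle(d[1, ], d[2, ], p), tolerance = 1e-12)
  }
})

test_that("classical MDS reproduces an exact planar configuration", {
  set.seed(41)
  pts <- cbind(runif(12), runif(12))
  d <- as.matrix(dist(pts))
  coords <- classical_mds(d, dims = 2)
  expect_lt(procrustes_rms(coords, pts), 1e-6)
  # sign convention: the largest-magnitude loading of each axis is positive
  for (k in 1:2) expect_gt(coords[which.max(abs(coords[, k])), k], 0)
})

test_that("group IBD summary aggregates pair means on the log scale", {
  pihat <- matrix(c(NA, 0.5, 0.1, 0.1,
                    0.5, NA, 0.1, 0.1,
                    0.1, 0.1, NA, 0.3,
                    0.1, 0.1, 0.3, NA), 4, 4)
  pops <- c("A", "A", "B", "B")
  gsum <- group_ibd_summary(pihat, pops)
  expect_equal(gsum["A", "A"], log(0.5))
  expect_equal(gsum["A", "B"], log(0.1))
  expect_equal(gsum["B", "B"], log(0.3))
  expect_equal(gsum["A", "B"], gsum["B", "A"])
})
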