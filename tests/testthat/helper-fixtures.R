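# Shared fixture builders: everything is generated in code at test time.

# A small genotype matrix from a plain dosage matrix (rows = samples).
toy_gm <- function(dos, pops = rep("P1", nrow(dos)), chrom = NULL,
                   pos = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  loci <- data.frame(
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    ref = "A", alt = "B", stringsAsFactors = FALSE
  )
  genotype_matrix(dos, paste0("s", seq_len(nrow(dos))), pops, loci)
}

# Single panmictic population scenario (no events).
panmictic_scenario <- function(pop = "A") {
  scenario(paste0("pan_", pop), pop,
           data.frame(time_param = character(), type = character(),
                      derived = character(), source1 = character(),
                      source2 = character(), prop_param = character(),
                      stringsAsFactors = FALSE),
           stats::setNames(paste0("N_", pop), pop))
}

# Two populations splitting at a fixed time.
split_scenario <- function(t_split, popA = "A", popB = "B") {
  scenario("split", c(popA, popB),
           data.frame(time_param = "t1", type = "divergence",
                      derived = popB, source1 = popA,
                      source2 = NA_character_, prop_param = NA_character_,
                      stringsAsFactors = FALSE),
           stats::setNames(paste0("N_", c(popA, popB)), c(popA, popB)))
}

# Independent transcription of the Weir-Cockerham (1984) two-population
# variance components, written scalar-by-scalar from the published component
# equations; serves as the oracle for the vectorized implementation.
wc84_oracle <- function(dA, dB) {
  m <- ncol(dA)
  a_sum <- 0; b_sum <- 0; c_sum <- 0
  for (l in seq_len(m)) {
    xa <- dA[, l][!is.na(dA[, l])]
    xb <- dB[, l][!is.na(dB[, l])]
    nA <- length(xa); nB <- length(xb)
    if (nA < 1 || nB < 1) next
    pA <- sum(xa) / (2 * nA); pB <- sum(xb) / (2 * nB)
    hA <- mean(xa == 1); hB <- mean(xb == 1)
    r <- 2
    nbar <- (nA + nB) / r
    if (nbar <= 1) next
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  a_sum / (a_sum + b_sum + c_sum)
}

# Random genotype matrix with two labelled populations (for oracle sweeps).
random_two_pop <- function(nA, nB, m, seed) {
  set.seed(seed)
  pA <- runif(m, 0.1, 0.9)
  pB <- runif(m, 0.1, 0.9)
  dA <- sapply(seq_len(m), function(l) rbinom(nA, 2, pA[l]))
  dB <- sapply(seq_len(m), function(l) rbinom(nB, 2, pB[l]))
  toy_gm(rbind(dA, dB), pops = c(rep("A", nA), rep("B", nB)))
}

# Procrustes RMS after optimal rotation/reflection + translation (for MDS
# recovery checks).
procrustes_rms <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$u %*% t(s$v)
  sqrt(mean((Xc %*% R - Yc)^2))
}
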