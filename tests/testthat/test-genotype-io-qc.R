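test_that("TSV dosage tables round-trip exactly", {
  g <- toy_gm(rbind(c(0, 2), c(1, NA), c(2, 0)), pops = c("X", "X", "Y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "tsv")
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_identical(g2$pop_labels, g$pop_labels)
  expect_identical(g2$loci$pos, g$loci$pos)
})

test_that("VCF input skips multi-allelic records with a warning and round-trips", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1\t0/0"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(g <- read_genotypes(path, "vcf"), "multi-allelic")
  expect_equal(n_loci(g), 2)
  expect_equal(unname(g$dosages[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(g$dosages[1, 2]))

  out <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, out)
  g2 <- read_genotypes(out, "vcf")
  expect_identical(unname(g2$dosages), unname(g$dosages))
})

test_that("PLINK text missing genotype '0 0' becomes a missing dosage", {
  ped <- c("fam1 s1 0 0 0 -9 A A A G",
           "fam1 s2 0 0 0 -9 A G 0 0",
           "fam2 s3 0 0 0 -9 G G G G")
  map <- c("1 snp1 0 100", "1 snp2 0 200")
  base <- withr::local_tempfile()
  writeLines(ped, paste0(base, ".ped"))
  writeLines(map, paste0(base, ".map"))
  g <- read_genotypes(paste0(base, ".ped"), "plink_text")
  expect_true(is.na(g$dosages[2, 2]))
  expect_identical(g$pop_labels, c("fam1", "fam1", "fam2"))
  # dosages count the lexicographically later (alt) allele
  expect_equal(unname(g$dosages[, 1]), c(0L, 1L, 2L))
})

test_that("SNP filter applies the NA-rate and MAF rules in order", {
  # locus 1: one missing of 4 (NA rate 0.25); locus 2: monomorphic;
  # locus 3: dosages (0,1,1,2), MAF 0.5 -> kept
  dos <- rbind(c(NA, 0, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, 2))
  g <- toy_gm(dos)
  res <- filter_snps(g)
  expect_equal(n_loci(res$genotypes), 1)
  expect_equal(res$report$n_snps_removed_narate, 1L)
  expect_equal(res$report$n_snps_removed_maf, 1L)
  expect_equal(unname(res$genotypes$dosages[, 1]), c(0L, 1L, 1L, 2L))

  # nothing violates the thresholds -> all kept
  g_ok <- toy_gm(matrix(rep(c(0, 2), 5 * 10), nrow = 10))
  expect_equal(n_loci(filter_snps(g_ok)$genotypes), 10)

  # min_maf = 0: only the NA-rate rule fires
  res0 <- filter_snps(g, min_maf = 0)
  expect_equal(n_loci(res0$genotypes), 2)
  expect_equal(res0$report$n_snps_removed_maf, 0L)
})

test_that("sample filter removes high-missingness individuals", {
  dos <- matrix(0L, 3, 20)
  dos[1, ] <- rep(c(0L, 2L), 10)
  dos[2, 1:2] <- NA  # 2/20 = 0.10 > 0.05
  g <- toy_gm(dos)
  res <- filter_samples(g)
  expect_equal(res$genotypes$sample_ids, c("s1", "s3"))
  expect_equal(res$report$n_samples_removed_narate, 1L)
  # vacuous threshold keeps everyone
  expect_equal(n_samples(filter_samples(g, max_na_rate = 1)$genotypes), 3)
  # no missing data -> all kept
  expect_equal(n_samples(filter_samples(toy_gm(dos[c(1, 3), ]))$genotypes), 2)
})

test_that("duplicate detection flags by mismatch fraction and components", {
  base <- rep(c(0L, 1L, 2L), length.out = 10)
  d2 <- base; d2[1:3] <- (base[1:3] + 1L) %% 3L  # 3/10 mismatch
  dos <- rbind(base, base, d2)
  g <- toy_gm(dos)
  dups <- find_duplicates(g)
  expect_equal(nrow(dups), 1)
  expect_equal(dups$mismatch_fraction, 0)
  expect_setequal(c(dups$sample_i, dups$sample_j), c("s1", "s2"))

  g2 <- deduplicate(g, dups)
  expect_equal(g2$sample_ids, c("s1", "s3"))

  # triple component: all pairwise below cutoff -> keep only the first
  dos3 <- rbind(base, base, base)
  g3 <- toy_gm(dos3)
  d3 <- find_duplicates(g3)
  expect_equal(nrow(d3), 3)
  expect_equal(deduplicate(g3, d3)$sample_ids, "s1")

  # deduplication is idempotent
  g4 <- deduplicate(g2, find_duplicates(g2))
  expect_identical(g4$sample_ids, g2$sample_ids)
})

test_that("QC report counts reconcile with dimension changes", {
  set.seed(42)
  dos <- matrix(rbinom(40 * 30, 2, 0.4), 40, 30)
  dos[sample(length(dos), 60)] <- NA
  g <- toy_gm(dos)
  res <- qc_pipeline(g, max_snp_na = 0.05, min_maf = 0.05,
                     max_sample_na = 0.10, dup_cutoff = 0.20)
  rep <- res$report
  expect_equal(rep$n_snps_removed_narate + rep$n_snps_removed_maf +
                 n_loci(res$genotypes), 30)
  expect_true(rep$n_samples_removed_narate >= 0)
  # each filtering operation is idempotent when applied to its own output
  g1 <- filter_snps(g, 0.05, 0.05)$genotypes
  expect_identical(filter_snps(g1, 0.05, 0.05)$genotypes$dosages, g1$dosages)
  g2 <- filter_samples(g, 0.10)$genotypes
  expect_identical(filter_samples(g2, 0.10)$genotypes$dosages, g2$dosages)
  gq <- res$genotypes
  expect_identical(deduplicate(gq, find_duplicates(gq))$dosages, gq$dosages)
})

test_that("VIF pruning removes collinear loci and nothing else", {
  set.seed(7)
  # mutually (nearly) independent loci: all kept
  dos <- matrix(rbinom(60 * 6, 2, 0.5), 60, 6)
  g <- toy_gm(dos)
  kept <- ld_prune(g, window_snps = 6, step_snps = 2, vif_threshold = 5)
  expect_equal(kept, 1:6)

  # an exact copy: the later-indexed duplicate is removed
  dos2 <- cbind(dos, dos[, 3])
  g2 <- toy_gm(dos2)
  kept2 <- ld_prune(g2, window_snps = 7, step_snps = 2, vif_threshold = 2)
  expect_false(7 %in% kept2)
  expect_true(3 %in% kept2)

  # pair engineered near r2 = 0.6 (VIF 2.5): exactly one of the pair pruned
  n <- 2000
  x <- rbinom(n, 2, 0.5)
  y <- ifelse(runif(n) < 0.775, x, rbinom(n, 2, 0.5))
  dos3 <- cbind(matrix(rbinom(n * 4, 2, 0.5), n, 4), x, y)
  g3 <- toy_gm(dos3)
  r2 <- cor(x, y)^2
  expect_gt(r2, 0.5)
  kept3 <- ld_prune(g3, window_snps = 6, step_snps = 2, vif_threshold = 2)
  expect_equal(length(setdiff(1:6, kept3)), 1)
  expect_true(setdiff(1:6, kept3) %in% 5:6)

  # invariant: recomputed VIFs among kept loci all below threshold
  xk <- dos3[, kept3]
  vifs <- vapply(seq_len(ncol(xk)), function(k) {
    fit <- stats::lm.fit(cbind(1, xk[, -k]), xk[, k])
    r2k <- 1 - sum(fit$residuals^2) / sum((xk[, k] - mean(xk[, k]))^2)
    1 / (1 - r2k)
  }, 1.0)
  expect_true(all(vifs < 2))

  expect_error(ld_prune(g, window_snps = 1), "window")
})

test_that("core selection greedily maximizes allele coverage", {
  # one heterozygous-everywhere sample covers every allele -> chosen first
  dos <- rbind(c(1, 1, 1), c(0, 0, 0), c(2, 2, 2))
  g <- toy_gm(dos)
  expect_equal(select_core(g, "P1", 1), "s1")
  expect_equal(allele_coverage(g, "s1"), 1)

  # size = population size covers everything observed
  expect_equal(allele_coverage(g, select_core(g, "P1", 3)), 1)

  # coverage is monotone non-decreasing in size
  set.seed(11)
  dos2 <- matrix(rbinom(8 * 12, 2, 0.3), 8, 12)
  g2 <- toy_gm(dos2)
  cov <- vapply(1:8, function(k) allele_coverage(g2, select_core(g2, "P1", k)),
                1.0)
  expect_true(all(diff(cov) >= -1e-12))

  # identical profiles: the duplicate cannot precede a sample adding alleles
  dos3 <- rbind(c(0, 0), c(0, 0), c(2, 2))
  g3 <- toy_gm(dos3)
  sel <- select_core(g3, "P1", 2)
  expect_equal(sel, c("s1", "s3"))

  expect_error(select_core(g, "P1", 0), "positive")
})
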