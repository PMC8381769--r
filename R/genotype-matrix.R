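#' Construct a genotype matrix
#'
#' The common currency of the pipeline: a samples x loci table of diploid
#' allele dosages (count of alternate alleles, 0/1/2, `NA` for missing calls)
#' together with a population label per sample and a genomic position per
#' locus.
#'
#' @param dosages integer matrix, samples in rows, loci in columns; entries
#'   0, 1, 2 or `NA`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param pop_labels character vector, one population name per sample.
#' @param loci data frame with columns `chrom`, `pos` (1-based physical
#'   position in base pairs), `ref`, `alt`. Loci must be sorted by position
#'   within chromosome; [genotype_matrix()] sorts them (and the dosage
#'   columns) if they are not.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, pop_labels, loci = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (length(sample_ids) != n)
    stop("`sample_ids` must have one entry per row of `dosages`")
  if (anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique")
  if (length(pop_labels) != n)
    stop("`pop_labels` must have one entry per sample")
  if (is.null(loci)) {
    loci <- data.frame(
      chrom = "chr1",
      pos = seq_len(m),
      ref = "A",
      alt = "B",
      stringsAsFactors = FALSE
    )
  }
  loci <- as.data.frame(loci)
  if (nrow(loci) != m)
    stop("`loci` must have one row per column of `dosages`")
  for (col in c("chrom", "pos", "ref", "alt"))
    if (is.null(loci[[col]])) stop("`loci` is missing column `", col, "`")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE))
    stop("dosages must be 0, 1, 2 or NA")
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(m))) {
    loci <- loci[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  rownames(loci) <- NULL
  rownames(dosages) <- sample_ids
  colnames(dosages) <- paste(loci$chrom, loci$pos, sep = ":")
  structure(
    list(
      dosages = dosages,
      sample_ids = as.character(sample_ids),
      pop_labels = as.character(pop_labels),
      loci = loci
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix> ", n_samples(x), " samples x ", n_loci(x), " loci; ",
    length(unique(x$pop_labels)), " population(s); ",
    sum(is.na(x$dosages)), " missing call(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / loci in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return An integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosages)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g a `genotype_matrix`.
#' @param samples indices or sample ids to keep (default all).
#' @param loci locus indices to keep (default all).
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  if (is.character(samples)) samples <- match(samples, g$sample_ids)
  if (anyNA(samples)) stop("unknown sample id in `samples`")
  if (is.null(loci)) loci <- seq_len(n_loci(g))
  genotype_matrix(
    g$dosages[samples, loci, drop = FALSE],
    g$sample_ids[samples],
    g$pop_labels[samples],
    g$loci[loci, , drop = FALSE]
  )
}

#' Validate the internal invariants of a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyDuplicated(g$sample_ids)) stop("sample ids are not unique")
  if (length(g$pop_labels) != n_samples(g)) stop("population labels missing")
  vals <- g$dosages[!is.na(g$dosages)]
  if (length(vals) && !all(vals %in% 0:2)) stop("invalid dosage values")
  o <- order(g$loci$chrom, g$loci$pos)
  if (!identical(o, seq_len(n_loci(g)))) stop("loci not sorted by (chrom, pos)")
  invisible(TRUE)
}

# ---- readers / writers ------------------------------------------------------

#' Read genotype data from standard formats
#'
#' Supports biallelic-SNP VCF (GT field), PLINK text (`.ped`/`.map`), and the
#' package's headered TSV dosage table. Multi-allelic VCF records are dropped
#' with a warning that reports how many were skipped.
#'
#' Population labels: the TSV format carries them in its second column and the
#' PLINK family-ID column is used as the population label. For VCF, supply
#' `pop_map` (named character vector, sample id -> population); samples
#' without an entry are labelled `"pop1"`.
#'
#' @param path path to the file (`.ped` for PLINK text; the matching `.map`
#'   is found by swapping the extension).
#' @param format one of `"vcf"`, `"plink_text"`, `"tsv"`.
#' @param pop_map optional named character vector mapping sample ids to
#'   population labels (used for VCF input).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_text"),
                           pop_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path, pop_map),
    plink_text = read_genotypes_ped(path)
  )
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("TSV dosage table needs sample_id, population and >=1 locus column")
  locus_names <- colnames(tab)[-(1:2)]
  parts <- strsplit(locus_names, ":", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("locus columns must be named chrom:pos[:ref:alt]")
  loci <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, function(p) if (length(p) >= 3) p[3] else "A", ""),
    alt = vapply(parts, function(p) if (length(p) >= 4) p[4] else "B", ""),
    stringsAsFactors = FALSE
  )
  dos <- as.matrix(tab[, -(1:2), drop = FALSE])
  genotype_matrix(dos, tab[[1]], tab[[2]], loci)
}

#' Write a genotype matrix
#'
#' `write_genotypes()` writes the package's TSV dosage dialect (first two
#' columns `sample_id` and `population`, then one `chrom:pos:ref:alt` column
#' per locus). `write_genotypes_vcf()` writes a minimal biallelic VCF
#' (gzipped, as `vcfR` writes it).
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_genotypes <- function(g, path) {
  locus_names <- paste(g$loci$chrom, g$loci$pos, g$loci$ref, g$loci$alt,
                       sep = ":")
  tab <- data.frame(
    sample_id = g$sample_ids,
    population = g$pop_labels,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  dos <- as.data.frame(g$dosages)
  colnames(dos) <- locus_names
  utils::write.table(cbind(tab, dos), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_genotypes_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic records in VCF")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  })
  samples <- colnames(gt)
  pops <- rep("pop1", length(samples))
  if (!is.null(pop_map)) {
    hit <- samples %in% names(pop_map)
    pops[hit] <- unname(pop_map[samples[hit]])
  }
  loci <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), samples, pops, loci)
}

#' @rdname write_genotypes
#' @export
write_genotypes_vcf <- function(g, path) {
  m <- n_loci(g)
  fix <- cbind(
    CHROM = as.character(g$loci$chrom),
    POS = as.character(g$loci$pos),
    ID = paste0("snp", seq_len(m)),
    REF = as.character(g$loci$ref),
    ALT = as.character(g$loci$alt),
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_chr <- matrix("./.", nrow = m, ncol = n_samples(g))
  d <- t(g$dosages)
  ok <- !is.na(d)
  gt_chr[ok] <- code[as.character(d[ok])]
  gt <- cbind("GT", gt_chr)
  colnames(gt) <- c("FORMAT", g$sample_ids)
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
    meta = c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
    fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  if (!file.exists(path) && file.exists(paste0(path, ".gz")))
    file.rename(paste0(path, ".gz"), path)
  invisible(path)
}

read_genotypes_ped <- function(path) {
  map_path <- paste0(tools::file_path_sans_ext(path), ".map")
  if (!file.exists(map_path)) stop("matching .map not found: ", map_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  # .map: chrom, snp id, genetic distance, position
  ped <- utils::read.table(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("inconsistent column count between .ped and .map")
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  n <- nrow(ped)
  dos <- matrix(NA_integer_, n, m)
  ref <- character(m)
  alt <- character(m)
  for (j in seq_len(m)) {
    a1 <- geno[, 2 * j - 1]
    a2 <- geno[, 2 * j]
    als <- c(a1, a2)
    obs <- sort(unique(als[als != "0"]))
    if (length(obs) > 2) stop("more than two alleles at locus ", j)
    ref[j] <- if (length(obs) >= 1) obs[1] else "A"
    alt[j] <- if (length(obs) == 2) obs[2] else "B"
    miss <- a1 == "0" | a2 == "0"
    dos[, j] <- (a1 == alt[j]) + (a2 == alt[j])
    dos[miss, j] <- NA_integer_
  }
  loci <- data.frame(chrom = as.character(map[[1]]), pos = as.integer(map[[4]]),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(dos, ped[[2]], ped[[1]], loci)
}

#' Allele frequency table stratified by population
#'
#' For each population and locus, the alternate-allele frequency among
#' non-missing calls and the number of observed gene copies (2 x non-missing
#' diploids).
#'
#' @param g a `genotype_matrix`.
#' @param pops populations to include (default: all, in order of first
#'   appearance).
#' @return A list with matrices `p` (frequency) and `n` (gene-copy counts),
#'   populations in rows, loci in columns.
#' @export
allele_freq_table <- function(g, pops = unique(g$pop_labels)) {
  p <- matrix(NA_real_, length(pops), n_loci(g),
              dimnames = list(pops, colnames(g$dosages)))
  n <- matrix(0L, length(pops), n_loci(g), dimnames = dimnames(p))
  for (k in seq_along(pops)) {
    rows <- g$pop_labels == pops[k]
    if (!any(rows)) stop("population not present: ", pops[k])
    d <- g$dosages[rows, , drop = FALSE]
    nn <- 2L * colSums(!is.na(d))
    tot <- colSums(d, na.rm = TRUE)
    p[k, ] <- ifelse(nn > 0, tot / nn, NA_real_)
    n[k, ] <- nn
  }
  list(p = p, n = n)
}
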