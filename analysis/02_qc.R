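#!/usr/bin/env Rscript
# Stage 2 — panel quality control.
#
# The standard array-panel filter sequence: drop SNPs with NA rate > 1%
# or MAF < 5%, drop samples with NA rate > 5%, then collapse duplicated
# (clonal) profiles at a 20% pairwise-mismatch cutoff, keeping the first
# member of each duplicate group. The result is the unique-genotype panel
# every later stage consumes.

library(vineflow)

g <- read_genotypes("results/study/panel.tsv", "tsv")
res <- qc_pipeline(g, max_snp_na = 0.01, min_maf = 0.05,
                   max_sample_na = 0.05, dup_cutoff = 0.20)

out_dir <- "results/qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_genotypes(res$genotypes, file.path(out_dir, "panel_filtered.tsv"))
rep <- res$report
jsonlite::write_json(
  list(n_snps_removed_narate = rep$n_snps_removed_narate,
       n_snps_removed_maf = rep$n_snps_removed_maf,
       n_samples_removed_narate = rep$n_samples_removed_narate,
       duplicate_pairs = rep$duplicate_pairs,
       n_samples_kept = n_samples(res$genotypes),
       n_snps_kept = n_loci(res$genotypes)),
  file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

print(rep)
manifest <- jsonlite::read_json("results/study/manifest.json")
truth_clones <- vapply(manifest$clone_pairs, function(p) p$clone, "")
found <- !(truth_clones %in% res$genotypes$sample_ids)
cat(sprintf("Recovered %d of %d injected clones as duplicates.\n",
            sum(found), length(truth_clones)))
cat(sprintf("Unique-genotype panel: %d samples x %d SNPs -> %s\n",
            n_samples(res$genotypes), n_loci(res$genotypes),
            file.path(out_dir, "panel_filtered.tsv")))
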