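#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study panel.
#
# We emulate the structure of an SNP-array germplasm panel: three
# populations related by a serial divergence history (Balkans ->
# Southern Italy -> Northern/Central Italy), array-like ascertainment
# (pooled MAF >= 5%), sporadic missing calls and a handful of clonal
# duplicates — the features the QC stage exists to handle. Ground truth
# (true scenario, parameters, clone pairs) goes into the manifest so
# later stages can be checked against it.

library(vineflow)

out_dir <- "results/study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fx <- separated_hypothesis1()
truth <- c(N_BALK = 1000, N_ITAP_south = 1000, N_ITAP_north_center = 1000,
           t1 = 100, t2 = 600)
cfg <- study_config(
  scenario = fx$scenarios[[1]],        # S1 is the true history
  params = truth,
  diploid_counts = c(BALK = 40, ITAP_south = 40, ITAP_north_center = 40),
  n_loci = 1500,
  snp_missing_rate = 0.004,
  sample_missing_rate = 0.002,
  n_clones = 6,
  clone_error_rate = 0.01,
  seed = 20240901
)
st <- generate_study(cfg)

write_genotypes(st$genotypes, file.path(out_dir, "panel.tsv"))
jsonlite::write_json(st$manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf(
  "Simulated %d samples x %d loci under scenario %s (t1 = %d, t2 = %d, Ne = %d);\n",
  n_samples(st$genotypes), n_loci(st$genotypes), st$manifest$scenario_id,
  truth[["t1"]], truth[["t2"]], truth[["N_BALK"]]))
cat(sprintf("injected %d missing calls and %d clonal duplicates.\n",
            st$manifest$n_missing_cells, nrow(st$manifest$clone_pairs)))
cat("Panel written to", file.path(out_dir, "panel.tsv"), "\n")
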