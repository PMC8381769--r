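#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with:
#' \describe{
#'   \item{input}{`list(path, format)` for observed data, or `genotypes`
#'     (a [genotype_matrix()] supplied in R).}
#'   \item{groups}{optional named list mapping sample id to analysis group;
#'     by default the panel's population labels are used.}
#'   \item{qc}{optional thresholds: `max_snp_na`, `min_maf`,
#'     `max_sample_na`, `dup_cutoff`.}
#'   \item{ld_decay}{optional: `pops` to compute LD-decay curves for,
#'     `max_dist_bp`, `core_size` (down-sample each group to a core of this
#'     size first; `NULL` uses all samples).}
#'   \item{ibd}{optional logical: compute the group-level IBD summary.}
#'   \item{hypotheses}{optional list; each entry has `name` (a
#'     [scenario_fixtures()] hypothesis name) or explicit `scenarios` +
#'     `priors`, and simulation settings `n_sims_per_scenario`, `n_loci`,
#'     `diploid_counts`, `tolerance`, `n_ppc`.}
#'   \item{seed}{integer; all stage seeds derive from it by fixed offsets
#'     (QC uses none, ABC hypothesis k uses `seed + 100*k`).}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @param genotypes optional pre-loaded [genotype_matrix()] (overrides
#'   `config$input`).
#' @return The normalized configuration (invisibly errors on problems).
#' @export
validate_run_config <- function(config, genotypes = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set `seed`")
  if (is.null(genotypes) && is.null(config$genotypes) &&
      is.null(config$input))
    stop("config must provide `input` (path + format) or `genotypes`")
  if (!is.null(config$input) && is.null(config$genotypes) &&
      is.null(genotypes)) {
    if (!file.exists(config$input$path))
      stop("input file not found: ", config$input$path)
  }
  qc_defaults <- list(max_snp_na = 0.01, min_maf = 0.05,
                      max_sample_na = 0.05, dup_cutoff = 0.20)
  config$qc <- utils::modifyList(qc_defaults, config$qc %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes QC, descriptive statistics, and per-hypothesis ABC model choice
#' in order, writing machine-readable outputs into `out_dir`: the QC report
#' (JSON), the Fst matrix (TSV) and its neighbor-joining tree (Newick),
#' per-group gene diversity (TSV), optional LD-decay curves and the IBD
#' group summary (TSV), one JSON + plain-text block per hypothesis
#' (posterior probabilities with 95% CIs and outlying-statistic counts at
#' p < 0.05 / p < 0.01), and a manifest with seeds and stage timings.
#' Completed-stage outputs are left intact if a later stage fails; failures
#' name the failing stage.
#'
#' @inheritParams validate_run_config
#' @param out_dir output directory (created if needed).
#' @param dry_run validate the configuration and return without computing.
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, genotypes = NULL,
                         dry_run = FALSE) {
  config <- validate_run_config(config, genotypes)
  if (dry_run) return(invisible(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  timings <- list()
  logln <- function(...) cat(..., "\n", sep = "", file = log_path,
                             append = TRUE)
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    logln("stage ", name, " done in ", sprintf("%.1f", timings[[name]]), "s")
    res
  }
  cat("", file = log_path)
  logln("seed: ", config$seed)

  g <- stage("load", function() {
    gg <- genotypes %||% config$genotypes
    if (is.null(gg))
      gg <- read_genotypes(config$input$path, config$input$format,
                           pop_map = config$input$pop_map %||% NULL)
    if (!is.null(config$groups)) {
      lab <- unlist(config$groups)[gg$sample_ids]
      if (anyNA(lab))
        stop("samples missing from the grouping map: ",
             paste(utils::head(gg$sample_ids[is.na(lab)], 5), collapse = ", "))
      gg$pop_labels <- unname(lab)
    }
    gg
  })

  qc <- stage("qc", function() {
    res <- qc_pipeline(g, config$qc$max_snp_na, config$qc$min_maf,
                       config$qc$max_sample_na, config$qc$dup_cutoff)
    rep <- res$report
    jsonlite::write_json(
      list(
        n_snps_removed_narate = rep$n_snps_removed_narate,
        n_snps_removed_maf = rep$n_snps_removed_maf,
        n_samples_removed_narate = rep$n_samples_removed_narate,
        duplicate_pairs = rep$duplicate_pairs,
        n_samples_kept = length(rep$kept_sample_ids),
        n_snps_kept = length(rep$kept_locus_indices)
      ),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  gq <- qc$genotypes
  pops <- unique(gq$pop_labels)

  stage("stats", function() {
    he <- vapply(pops, function(p) gene_diversity(gq, p), 1.0)
    utils::write.table(
      data.frame(group = pops, gene_diversity = he),
      file.path(out_dir, "gene_diversity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(pops) >= 2) {
      fm <- fst_matrix(gq, pops)
      utils::write.table(fm, file.path(out_dir, "fst_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      if (length(pops) >= 3)
        writeLines(nj_tree(fm), file.path(out_dir, "nj_tree.nwk"))
    }
    if (!is.null(config$ld_decay)) {
      ld_pops <- config$ld_decay$pops %||% pops
      for (p in ld_pops) {
        gp <- gq
        core <- config$ld_decay$core_size
        if (!is.null(core) && sum(gq$pop_labels == p) > core) {
          ids <- select_core(gq, p, core)
          gp <- subset_genotypes(gq, samples = ids)
        }
        ld <- ld_decay(gp, pop = p,
                       max_dist_bp = config$ld_decay$max_dist_bp %||% 1e7)
        out <- ld$curve[ld$curve$n_pairs > 0, ]
        utils::write.table(out,
          file.path(out_dir, paste0("ld_decay_", p, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (isTRUE(config$ibd)) {
      pihat <- ibd_all_pairs(gq)
      gsum <- group_ibd_summary(pihat, gq$pop_labels)
      utils::write.table(gsum, file.path(out_dir, "ibd_group_summary.tsv"),
                         sep = "\t", quote = FALSE)
    }
    NULL
  })

  if (!is.null(config$hypotheses)) {
    fixtures <- scenario_fixtures()
    for (k in seq_along(config$hypotheses)) {
      hy <- config$hypotheses[[k]]
      hname <- hy$name %||% paste0("hypothesis", k)
      stage(paste0("abc_", hname), function() {
        if (!is.null(hy$name)) {
          fx <- fixtures[[hy$name]]
          if (is.null(fx)) stop("unknown hypothesis fixture: ", hy$name)
          scenarios <- fx$scenarios; priors <- fx$priors
          hpops <- fx$pops
        } else {
          scenarios <- hy$scenarios; priors <- hy$priors
          hpops <- hy$pops
        }
        absent <- setdiff(hpops, pops)
        if (length(absent))
          stop("hypothesis population(s) absent from the data: ",
               paste(absent, collapse = ", "))
        counts <- hy$diploid_counts %||%
          stats::setNames(as.list(table(gq$pop_labels)[hpops]), hpops)
        counts <- stats::setNames(as.integer(unlist(counts[hpops])), hpops)
        hseed <- config$seed + 100L * k
        obs <- summary_vector(gq, hpops)
        ref <- build_reference_table(
          scenarios, priors, counts, hy$n_loci %||% 500,
          hy$n_sims_per_scenario %||% 1000, seed = hseed)
        mc <- model_choice(ref, obs, hy$tolerance %||% 0.01,
                           bootstrap_B = hy$bootstrap_B %||% 100,
                           seed = hseed + 1L)
        tab <- mc$table
        tab$outliers_p05 <- NA_integer_
        tab$outliers_p01 <- NA_integer_
        rej <- abc_reject(ref, obs, hy$tolerance %||% 0.01)
        for (si in seq_along(scenarios)) {
          sid <- scenarios[[si]]$id
          chk <- tryCatch({
            post <- adjust_parameters(ref, obs, sid, priors[[si]],
                                      rejection = rej)
            model_check(scenarios[[si]], post, counts,
                        hy$n_loci %||% 500, hy$n_ppc %||% 100, obs, ref,
                        seed = hseed + 10L + si)
          }, error = function(e) NULL)
          if (!is.null(chk)) {
            tab$outliers_p05[tab$scenario == sid] <- chk$outliers_p05
            tab$outliers_p01[tab$scenario == sid] <- chk$outliers_p01
          }
        }
        sel_tab <- tab
        sel_tab$n_outliers <- ifelse(
          is.na(tab$outliers_p05), 2L * length(obs),
          tab$outliers_p05 + tab$outliers_p01)
        sel <- select_best_scenario(sel_tab)
        jsonlite::write_json(
          list(hypothesis = hname, selected = sel$selected,
               pp_selected = sel$pp, table = tab, seed = hseed),
          file.path(out_dir, paste0("abc_", hname, ".json")),
          auto_unbox = TRUE, digits = NA)
        writeLines(
          c(sprintf("%-12s %10s %10s %10s", hname,
                    tab$scenario[1], tab$scenario[2], tab$scenario[3]),
            sprintf("%-12s %10.0f %10.0f %10.0f", "Pp (%)",
                    tab$pp[1], tab$pp[2], tab$pp[3]),
            sprintf("%-12s %4.0f-%-5.0f %4.0f-%-5.0f %4.0f-%-5.0f", "95% CI",
                    tab$ci_lo[1], tab$ci_hi[1], tab$ci_lo[2], tab$ci_hi[2],
                    tab$ci_lo[3], tab$ci_hi[3]),
            "Number of outlying statistics",
            sprintf("%-12s %10.0f %10.0f %10.0f", "P < 0.05",
                    tab$outliers_p05[1], tab$outliers_p05[2],
                    tab$outliers_p05[3]),
            sprintf("%-12s %10.0f %10.0f %10.0f", "P < 0.01",
                    tab$outliers_p01[1], tab$outliers_p01[2],
                    tab$outliers_p01[3]),
            sprintf("selected: %s (Pp %.0f%%)", sel$selected, sel$pp)),
          file.path(out_dir, paste0("abc_", hname, ".txt")))
        NULL
      })
    }
  }

  jsonlite::write_json(
    list(seed = config$seed, timings = timings,
         n_samples = n_samples(gq), n_loci = n_loci(gq)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
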