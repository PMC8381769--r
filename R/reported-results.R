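#' Published full-panel model-choice summaries (worked-example fixture)
#'
#' The per-scenario posterior probabilities (percent), 95% confidence
#' intervals and outlying-statistic counts reported by the published
#' full-panel analysis of Eurasian grapevine germplasm (1,038 varieties,
#' ~7k SNPs) for the four dissemination hypotheses. The genotype panel
#' itself is not publicly deposited, so these printed summaries serve as
#' the worked example for [select_best_scenario()]: feeding each
#' hypothesis block through the selection rule reproduces the reported
#' scenario choices.
#'
#' @param hypothesis optional hypothesis name (`"hypothesis1"` ..
#'   `"hypothesis4"`); `NULL` returns all rows.
#' @return Data frame with columns `hypothesis`, `scenario`, `pp`,
#'   `ci_lo`, `ci_hi`, `outliers_p05`, `outliers_p01`.
#' @export
reported_model_choice <- function(hypothesis = NULL) {
  path <- system.file("extdata", "reported_model_choice.csv",
                      package = "vineflow", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(hypothesis)) {
    tab <- tab[tab$hypothesis == hypothesis, , drop = FALSE]
    if (nrow(tab) == 0) stop("unknown hypothesis: ", hypothesis)
    rownames(tab) <- NULL
  }
  tab
}
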