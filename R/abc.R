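#' Summary-statistic vector for ABC
#'
#' The low-dimensional dataset description used for scenario comparison:
#' per-population mean gene diversity (in the supplied population order),
#' then pairwise Weir-Cockerham Fst for all population pairs (pair order
#' (1,2), (1,3), ..., i.e. lexicographic in the supplied order), then
#' pairwise Nei standard distances in the same pair order. Length
#' P + 2 * choose(P, 2): 9 statistics for three populations. Infinite Nei
#' distances (disjoint fixed alleles) are capped at 10.0 so every entry is
#' finite.
#'
#' @param g a [genotype_matrix()].
#' @param pops ordered population names (>= 2 samples each).
#' @return Named numeric vector.
#' @export
summary_vector <- function(g, pops) {
  P <- length(pops)
  for (pp in pops)
    if (sum(g$pop_labels == pp) < 2)
      stop("population ", pp, " has fewer than 2 samples")
  ft <- allele_freq_table(g, pops)
  he <- vapply(seq_len(P), function(k)
    mean(gene_diversity_from_freqs(ft$p[k, ], ft$n[k, ])), 1.0)
  names(he) <- paste0("He_", pops)
  prs <- utils::combn(P, 2)
  fst <- numeric(ncol(prs)); nei <- numeric(ncol(prs))
  fn <- character(ncol(prs)); nn <- character(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    # a pair identically fixed at every locus has no usable locus for the
    # variance-components estimator; for the summary vector that reads as
    # zero differentiation
    fst[k] <- tryCatch(pairwise_fst(g, pops[i], pops[j]),
                       error = function(e) 0)
    nei[k] <- nei_distance_from_freqs(ft$p[i, ], ft$p[j, ], ft$n[i, ], ft$n[j, ])
    fn[k] <- paste0("Fst_", pops[i], "_", pops[j])
    nn[k] <- paste0("Nei_", pops[i], "_", pops[j])
  }
  nei[!is.finite(nei)] <- 10.0
  names(fst) <- fn; names(nei) <- nn
  c(he, fst, nei)
}

#' Build an ABC reference table
#'
#' For each scenario, `n_sims_per_scenario` datasets are simulated from
#' prior-drawn parameters and summarized with [summary_vector()]. Rows are
#' generated scenario by scenario in a fixed order, so the table is
#' reproducible from the seed.
#'
#' @param scenarios list of [scenario()] objects (one hypothesis).
#' @param priors list of [prior_spec()], one per scenario.
#' @param diploid_counts named integer vector of diploids per population.
#' @param n_loci SNP loci per simulated dataset.
#' @param n_sims_per_scenario simulations per scenario.
#' @param seed integer seed for the whole table.
#' @param min_maf pooled minor-allele-frequency condition applied inside the
#'   simulations (mirror of the observed-panel filter).
#' @return An object of class `reference_table`: `scenario` (factor),
#'   `params` (data frame, `NA` for parameters a scenario lacks), `stats`
#'   (matrix), `pops`.
#' @export
build_reference_table <- function(scenarios, priors, diploid_counts, n_loci,
                                  n_sims_per_scenario, seed = 1,
                                  min_maf = 0.05) {
  stopifnot(length(scenarios) == length(priors))
  set.seed(seed)
  pops <- names(diploid_counts)
  all_params <- unique(unlist(lapply(scenarios, scenario_params)))
  rows_sc <- character(0)
  par_list <- list()
  stat_list <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    for (r in seq_len(n_sims_per_scenario)) {
      th <- draw_parameters(s, priors[[si]])
      g <- simulate_dataset(s, th, diploid_counts, n_loci, min_maf = min_maf)
      stat_list[[length(stat_list) + 1L]] <- summary_vector(g, pops)
      row <- stats::setNames(rep(NA_real_, length(all_params)), all_params)
      row[names(th)] <- th
      par_list[[length(par_list) + 1L]] <- row
      rows_sc <- c(rows_sc, s$id)
    }
  }
  structure(
    list(
      scenario = factor(rows_sc, levels = vapply(scenarios, `[[`, "", "id")),
      params = as.data.frame(do.call(rbind, par_list)),
      stats = do.call(rbind, stat_list),
      pops = pops
    ),
    class = "reference_table"
  )
}

#' @export
print.reference_table <- function(x, ...) {
  cat("<reference_table> ", nrow(x$stats), " simulations, ",
      nlevels(x$scenario), " scenario(s), ", ncol(x$stats),
      " summary statistics\n", sep = "")
  invisible(x)
}

# Standardization constants over the full table; zero-variance statistics are
# dropped (with a warning) since they carry no distance information.
ref_standardizer <- function(ref) {
  ctr <- colMeans(ref$stats)
  scl <- apply(ref$stats, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance statistic(s) dropped")
  list(center = ctr, scale = scl, keep = keep)
}

standardize_stats <- function(x, std) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  sweep(sweep(x[, std$keep, drop = FALSE], 2, std$center[std$keep]),
        2, std$scale[std$keep], "/")
}

#' ABC rejection step
#'
#' Distances are Euclidean norms on per-statistic standardized values
#' (center and scale estimated from the full reference table). The
#' `ceiling(tolerance * N)` closest rows are retained; boundary ties are
#' broken by row index.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed a [summary_vector()] for the observed data.
#' @param tolerance retained fraction of simulations (0 < tolerance <= 1).
#' @return list(`indices` (retained row indices), `distances` (their
#'   distances, ascending), `std` (standardization constants)).
#' @export
abc_reject <- function(ref, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  std <- ref_standardizer(ref)
  zs <- standardize_stats(ref$stats, std)
  zo <- standardize_stats(observed, std)
  d <- sqrt(rowSums(sweep(zs, 2, zo[1, ])^2))
  n_keep <- ceiling(tolerance * nrow(zs))
  ord <- order(d, seq_along(d))
  idx <- ord[seq_len(n_keep)]
  list(indices = idx, distances = d[idx], std = std)
}

# Epanechnikov kernel weights on rejection distances.
epanechnikov_w <- function(distances) {
  dmax <- max(distances)
  if (dmax == 0) return(rep(1, length(distances)))
  pmax(1 - (distances / dmax)^2, 1e-8)
}

#' ABC model choice by weighted multinomial logistic regression
#'
#' After rejection, scenario posterior probabilities are estimated two
#' ways: the direct (rejection) estimate is the per-scenario fraction of
#' retained rows; the logistic estimate regresses the scenario label on the
#' standardized summary statistics over the retained rows (weighted by the
#' Epanechnikov kernel of the rejection distances, with a tiny ridge
#' penalty against complete separation) and evaluates the fit at the
#' observed vector. 95% confidence intervals come from percentile bootstrap
#' over the retained rows.
#'
#' @inheritParams abc_reject
#' @param bootstrap_B bootstrap resamples for the CI (0 disables the CI).
#' @param seed optional seed (bootstrap reproducibility).
#' @param ridge weight-decay penalty passed to the multinomial fit.
#' @return An object of class `model_choice_result`: data frame `table`
#'   with `scenario`, `pp` (logistic posterior probability, percent),
#'   `ci_lo`, `ci_hi`, `direct` (percent), plus `retained` indices and
#'   `distances`.
#' @export
model_choice <- function(ref, observed, tolerance = 0.01, bootstrap_B = 100,
                         seed = NULL, ridge = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  if (nlevels(ref$scenario) < 2) stop("need at least 2 scenarios")
  rej <- abc_reject(ref, observed, tolerance)
  idx <- rej$indices
  z <- standardize_stats(ref$stats, rej$std)[idx, , drop = FALSE]
  zo <- standardize_stats(observed, rej$std)
  lab <- ref$scenario[idx]
  w <- epanechnikov_w(rej$distances)
  levs <- levels(ref$scenario)
  absent <- setdiff(levs, unique(as.character(lab)))
  if (length(absent))
    warning("scenario(s) absent from retained rows: ",
            paste(absent, collapse = ", "))
  pp <- fit_predict_multinom(z, lab, w, zo, ridge)
  direct <- as.numeric(table(lab)[levs]) / length(idx)
  direct[is.na(direct)] <- 0
  ci <- matrix(NA_real_, length(levs), 2)
  if (bootstrap_B > 0) {
    boot <- matrix(NA_real_, bootstrap_B, length(levs))
    for (b in seq_len(bootstrap_B)) {
      take <- sample.int(length(idx), replace = TRUE)
      boot[b, ] <- fit_predict_multinom(z[take, , drop = FALSE], lab[take],
                                        w[take], zo, ridge)
    }
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    # percentile intervals are widened, if needed, to contain the point
    # estimate so downstream overlap checks stay coherent
    ci[, 1] <- pmin(ci[, 1], pp)
    ci[, 2] <- pmax(ci[, 2], pp)
  }
  structure(
    list(
      table = data.frame(
        scenario = levs,
        pp = 100 * pp,
        ci_lo = 100 * ci[, 1],
        ci_hi = 100 * ci[, 2],
        direct = 100 * direct,
        stringsAsFactors = FALSE
      ),
      retained = idx,
      distances = rej$distances
    ),
    class = "model_choice_result"
  )
}

# Weighted multinomial logistic fit + prediction at one point. Degenerate
# label sets (a single scenario retained) short-circuit to a point mass.
fit_predict_multinom <- function(z, lab, w, zo, ridge = 1e-6) {
  levs <- levels(lab)
  present <- levs[levs %in% unique(as.character(lab))]
  out <- stats::setNames(rep(0, length(levs)), levs)
  if (length(present) == 1) {
    out[present] <- 1
    return(out)
  }
  df <- data.frame(.y = factor(as.character(lab), levels = present),
                   z, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = df, weights = w, decay = ridge,
                        trace = FALSE, maxit = 500, MaxNWts = 5000)
  nd <- as.data.frame(zo)
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  if (length(present) == 2) {
    # binary fits return P(second level)
    out[present[2]] <- as.numeric(pr)
    out[present[1]] <- 1 - as.numeric(pr)
  } else {
    if (is.matrix(pr)) pr <- pr[1, ]
    out[names(pr)] <- as.numeric(pr)
  }
  out / sum(out)
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("<model_choice_result> (", length(x$retained), " retained)\n", sep = "")
  tab <- x$table
  for (k in seq_len(nrow(tab)))
    cat(sprintf("  %-4s Pp %5.1f%%  [%5.1f, %5.1f]  direct %5.1f%%\n",
                tab$scenario[k], tab$pp[k], tab$ci_lo[k], tab$ci_hi[k],
                tab$direct[k]))
  invisible(x)
}

#' Apply the scenario-selection rule
#'
#' Ranks competing scenarios by logistic posterior probability; the winner
#' is the highest-Pp scenario, with ties broken by fewest total outlying
#' statistics and then by input order. The returned trace flags (a) whether
#' the winner's 95% CI overlaps the runner-up's and (b) whether the winner
#' also minimizes the total outlying-statistic count — the remaining
#' goodness-of-fit criteria of the selection rule.
#'
#' @param table data frame with columns `scenario`, `pp`, and either
#'   `n_outliers` or both `outliers_p05` and `outliers_p01`; optional
#'   `ci_lo`, `ci_hi`.
#' @return list(`selected`, `pp`, `ci_overlap_runner_up`,
#'   `winner_minimizes_outliers`, `trace` (ranked data frame)).
#' @export
select_best_scenario <- function(table) {
  tab <- as.data.frame(table)
  if (nrow(tab) < 2) stop("need at least 2 scenarios")
  if (is.null(tab$n_outliers)) {
    if (is.null(tab$outliers_p05) || is.null(tab$outliers_p01))
      stop("supply `n_outliers` or both `outliers_p05` and `outliers_p01`")
    tab$n_outliers <- tab$outliers_p05 + tab$outliers_p01
  }
  ord <- order(-tab$pp, tab$n_outliers, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  winner <- tab[1, ]
  runner <- tab[2, ]
  overlap <- NA
  if (!is.null(tab$ci_lo) && !is.null(tab$ci_hi) &&
      is.finite(winner$ci_lo) && is.finite(runner$ci_hi))
    overlap <- winner$ci_lo <= runner$ci_hi
  list(
    selected = winner$scenario,
    pp = winner$pp,
    ci_overlap_runner_up = overlap,
    winner_minimizes_outliers = winner$n_outliers == min(tab$n_outliers),
    trace = tab
  )
}

#' Local-linear ABC parameter adjustment on the logit scale
#'
#' Each parameter of the retained simulations is mapped to the real line by
#' the logit of its position inside its prior bounds [a, b],
#' z = ln((theta - a)/(b - theta)); a weighted linear regression of z on the
#' standardized summary statistics (Epanechnikov weights from the rejection
#' distances) is then used to shift every retained draw to the observed
#' vector, z* = z - b' (S - s_obs); back-transforming guarantees the
#' adjusted values stay strictly inside the prior bounds. Parameters with
#' degenerate (point) priors pass through unchanged.
#'
#' @inheritParams abc_reject
#' @param scenario_id scenario whose retained draws to adjust.
#' @param rejection result of [abc_reject()] (recomputed when `NULL`).
#' @return Data frame of adjusted parameter draws (posterior sample).
#' @export
adjust_parameters <- function(ref, observed, scenario_id, priors,
                              tolerance = 0.01, rejection = NULL) {
  if (is.null(rejection)) rejection <- abc_reject(ref, observed, tolerance)
  sel <- rejection$indices[ref$scenario[rejection$indices] == scenario_id]
  dsel <- rejection$distances[ref$scenario[rejection$indices] == scenario_id]
  if (length(sel) == 0) stop("no retained rows for scenario ", scenario_id)
  z <- standardize_stats(ref$stats, rejection$std)[sel, , drop = FALSE]
  zo <- standardize_stats(observed, rejection$std)
  w <- epanechnikov_w(dsel)
  pars <- ref$params[sel, , drop = FALSE]
  pars <- pars[, colSums(!is.na(pars)) > 0, drop = FALSE]
  if (length(sel) < ncol(z) + 2)
    stop("need at least ", ncol(z) + 2, " retained rows for the regression")
  out <- pars
  for (nm in colnames(pars)) {
    pr <- priors$params[[nm]]
    if (is.null(pr)) stop("no prior for parameter ", nm)
    a <- pr$min; b <- pr$max
    if (a == b) { out[[nm]] <- pars[[nm]]; next }
    th <- pmin(pmax(pars[[nm]], a + 1e-12 * (b - a)), b - 1e-12 * (b - a))
    zt <- log((th - a) / (b - th))
    X <- cbind(1, sweep(z, 2, zo[1, ]))
    fit <- stats::lm.wfit(X, zt, w)
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    zt_adj <- zt - as.numeric(sweep(z, 2, zo[1, ]) %*% beta)
    out[[nm]] <- (a + b * exp(zt_adj)) / (1 + exp(zt_adj))
    big <- zt_adj > 700
    out[[nm]][big] <- b - 1e-12 * (b - a)
  }
  out
}

#' Scenario-discrimination (confusion) analysis
#'
#' Simulates `n_pods_per_scenario` pseudo-observed datasets per scenario
#' from its priors, classifies each by the highest logistic posterior
#' probability against a shared reference table, and reports per-scenario
#' type-I error (datasets from the scenario not assigned to it), type-II
#' error (datasets from other scenarios wrongly assigned to it, out of all
#' such datasets), and overall performance (fraction correctly classified).
#'
#' @inheritParams build_reference_table
#' @param n_pods_per_scenario pseudo-observed datasets per scenario.
#' @param tolerance rejection tolerance for each classification.
#' @param ref optional pre-built reference table (built internally
#'   otherwise).
#' @return An object of class `confusion_report`: `confusion` matrix
#'   (true x assigned counts), `type1`, `type2`, `performance`.
#' @export
confusion_analysis <- function(scenarios, priors, diploid_counts, n_loci,
                               n_sims_per_scenario = 1000,
                               n_pods_per_scenario = 20, tolerance = 0.01,
                               seed = 1, min_maf = 0.05, ref = NULL) {
  if (is.null(ref))
    ref <- build_reference_table(scenarios, priors, diploid_counts, n_loci,
                                 n_sims_per_scenario, seed = seed,
                                 min_maf = min_maf)
  set.seed(seed + 1L)
  levs <- levels(ref$scenario)
  conf <- matrix(0L, length(levs), length(levs),
                 dimnames = list(true = levs, assigned = levs))
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    for (r in seq_len(n_pods_per_scenario)) {
      th <- draw_parameters(s, priors[[si]])
      gpod <- simulate_dataset(s, th, diploid_counts, n_loci,
                               min_maf = min_maf)
      obs <- summary_vector(gpod, ref$pops)
      mc <- model_choice(ref, obs, tolerance, bootstrap_B = 0)
      assigned <- mc$table$scenario[which.max(mc$table$pp)]
      conf[s$id, assigned] <- conf[s$id, assigned] + 1L
    }
  }
  n_pods <- rowSums(conf)
  type1 <- 1 - diag(conf) / n_pods
  type2 <- vapply(seq_along(levs), function(k) {
    others <- setdiff(seq_along(levs), k)
    sum(conf[others, k]) / sum(n_pods[others])
  }, 1.0)
  names(type2) <- levs
  structure(
    list(confusion = conf, type1 = type1, type2 = type2,
         performance = sum(diag(conf)) / sum(conf)),
    class = "confusion_report"
  )
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> performance ",
      sprintf("%.1f%%", 100 * x$performance), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Posterior-predictive model checking
#'
#' Simulates `n_ppc` datasets with parameters resampled from the posterior
#' sample of the selected scenario and compares each observed summary
#' statistic with its posterior-predictive distribution: the two-sided tail
#' probability p_k = 2 min(F(s_obs_k), 1 - F(s_obs_k)) with F the empirical
#' predictive CDF. Reports the counts of outlying statistics at p < 0.05
#' and p < 0.01 and a principal-component projection (top two components of
#' the standardized reference statistics) of the reference simulations, the
#' predictive simulations and the observed point.
#'
#' @inheritParams build_reference_table
#' @param s the selected [scenario()].
#' @param posterior data frame of adjusted parameter draws
#'   ([adjust_parameters()]).
#' @param n_ppc number of posterior-predictive datasets.
#' @param observed the observed [summary_vector()].
#' @param ref reference table (for the principal-component plane).
#' @return An object of class `model_check_report`: `tail_prob` per
#'   statistic, `outliers_p05`, `outliers_p01`, and `pca` (list with
#'   `reference`, `predictive`, `observed` coordinates).
#' @export
model_check <- function(s, posterior, diploid_counts, n_loci, n_ppc,
                        observed, ref, seed = 1, min_maf = 0.05) {
  set.seed(seed)
  stats_ppc <- matrix(NA_real_, n_ppc, length(observed),
                      dimnames = list(NULL, names(observed)))
  for (r in seq_len(n_ppc)) {
    th <- unlist(posterior[sample.int(nrow(posterior), 1), , drop = TRUE])
    g <- simulate_dataset(s, th, diploid_counts, n_loci, min_maf = min_maf)
    stats_ppc[r, ] <- summary_vector(g, ref$pops)
  }
  tail_prob <- vapply(seq_along(observed), function(k) {
    f <- mean(stats_ppc[, k] <= observed[k])
    2 * min(f, 1 - f)
  }, 1.0)
  names(tail_prob) <- names(observed)
  std <- ref_standardizer(ref)
  zr <- standardize_stats(ref$stats, std)
  pca <- stats::prcomp(zr, center = FALSE, scale. = FALSE)
  proj <- function(x) standardize_stats(x, std) %*% pca$rotation[, 1:2]
  structure(
    list(
      tail_prob = tail_prob,
      outliers_p05 = sum(tail_prob < 0.05),
      outliers_p01 = sum(tail_prob < 0.01),
      pca = list(reference = zr %*% pca$rotation[, 1:2],
                 predictive = proj(stats_ppc),
                 observed = proj(observed))
    ),
    class = "model_check_report"
  )
}

#' @export
print.model_check_report <- function(x, ...) {
  cat("<model_check_report> outlying statistics: ", x$outliers_p05,
      " at p<0.05, ", x$outliers_p01, " at p<0.01 (of ",
      length(x$tail_prob), ")\n", sep = "")
  invisible(x)
}
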