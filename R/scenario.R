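#' Define a demographic scenario
#'
#' A scenario is a backward-time demographic model over named populations:
#' a list of divergence events (all lineages of a derived population move
#' into a source population at time t) and admixture events (each lineage of
#' the admixed population moves, independently, to source A with probability
#' r and to source B otherwise), ending in a single root population. Times
#' are in generations before present; every population branch carries its
#' own diploid effective size Ne.
#'
#' Event times, effective sizes and admixture proportions are *symbolic*
#' parameter names (e.g. `"t1"`, `"N_BALK"`, `"r"`); concrete values come
#' from a [prior_spec()] via [draw_parameters()].
#'
#' @param id scenario identifier.
#' @param pops character vector of sampled population names.
#' @param events data frame with columns `time_param`, `type`
#'   (`"divergence"` or `"admixture"`), `derived`, `source1`, `source2`
#'   (`NA` for divergence), `prop_param` (`NA` for divergence). Events must
#'   be listed in ascending time order (enforced through the prior's
#'   ordering constraints).
#' @param ne_params named character vector mapping each population to its
#'   effective-size parameter name.
#' @return An object of class `scenario`.
#' @export
scenario <- function(id, pops, events, ne_params) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  needed <- c("time_param", "type", "derived", "source1", "source2",
              "prop_param")
  for (col in needed) if (is.null(events[[col]]))
    stop("`events` is missing column `", col, "`")
  structure(
    list(id = id, pops = as.character(pops), events = events,
         ne_params = ne_params),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario ", x$id, "> populations: ", paste(x$pops, collapse = ", "),
      "\n", sep = "")
  for (k in seq_len(nrow(x$events))) {
    e <- x$events[k, ]
    if (e$type == "divergence")
      cat("  t=", e$time_param, ": ", e$derived, " -> ", e$source1, "\n",
          sep = "")
    else
      cat("  t=", e$time_param, ": ", e$derived, " <- admix(", e$source1,
          ", ", e$source2, "; r=", e$prop_param, ")\n", sep = "")
  }
  invisible(x)
}

#' Parameter names used by a scenario
#' @param s a `scenario`.
#' @return Character vector of parameter names (sizes, times, proportions).
#' @export
scenario_params <- function(s) {
  unique(c(unname(s$ne_params), s$events$time_param,
           stats::na.omit(s$events$prop_param)))
}

#' Prior specification for scenario parameters
#'
#' @param params named list; each element is `list(dist, min, max)` with
#'   `dist` one of `"uniform"`, `"loguniform"`.
#' @param constraints list of 2-element character vectors
#'   `c(larger, smaller)` imposing `larger > smaller` on time parameters.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(params, constraints = list()) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!p$dist %in% c("uniform", "loguniform"))
      stop("unknown distribution for ", nm)
    if (!(p$min <= p$max)) stop("min > max for ", nm)
  }
  structure(list(params = params, constraints = constraints),
            class = "prior_spec")
}

#' Default priors for a scenario
#'
#' Effective sizes: log-uniform on [100, 10,000] diploids. Event times
#' (generations): t1 ~ U[10, 500], later times ~ U[10, 2,000] with ordering
#' enforced by constraint. Admixture proportions ~ U[0.05, 0.95].
#'
#' @param s a `scenario`.
#' @return A [prior_spec()].
#' @export
default_priors <- function(s) {
  params <- list()
  for (nm in unname(s$ne_params))
    params[[nm]] <- list(dist = "loguniform", min = 100, max = 10000)
  tp <- s$events$time_param
  for (k in seq_along(tp)) {
    params[[tp[k]]] <-
      if (k == 1) list(dist = "uniform", min = 10, max = 500)
      else list(dist = "uniform", min = 10, max = 2000)
  }
  for (rp in stats::na.omit(s$events$prop_param))
    params[[rp]] <- list(dist = "uniform", min = 0.05, max = 0.95)
  constraints <- list()
  if (length(tp) >= 2)
    for (k in seq(2, length(tp)))
      constraints[[length(constraints) + 1]] <- c(tp[k], tp[k - 1])
  prior_spec(params, constraints)
}

#' Point priors at fixed parameter values
#'
#' @param values named numeric vector of parameter values.
#' @return A degenerate [prior_spec()] whose draws equal `values` exactly.
#' @export
point_priors <- function(values) {
  params <- lapply(values, function(v) list(dist = "uniform", min = v, max = v))
  names(params) <- names(values)
  prior_spec(params)
}

#' Validate a scenario against its structural invariants
#'
#' Checks that the event list references declared populations, that the
#' backward-time process merges every sampled population into a single root,
#' and (when a prior is supplied) that time parameters are positive and
#' admixture proportions lie strictly inside (0, 1).
#'
#' @param s a `scenario`.
#' @param priors optional [prior_spec()] to check bounds against.
#' @return Character vector of violations; empty if the scenario is valid.
#' @export
validate_scenario <- function(s, priors = NULL) {
  v <- character(0)
  alive <- s$pops
  ev <- s$events
  for (k in seq_len(nrow(ev))) {
    e <- ev[k, ]
    if (!(e$derived %in% alive)) {
      v <- c(v, paste0("event ", k, ": derived population `", e$derived,
                       "` not alive"))
      next
    }
    if (e$type == "divergence") {
      if (!(e$source1 %in% alive))
        v <- c(v, paste0("event ", k, ": source `", e$source1, "` not alive"))
      alive <- setdiff(alive, e$derived)
    } else if (e$type == "admixture") {
      if (!all(c(e$source1, e$source2) %in% c(alive, e$derived)))
        v <- c(v, paste0("event ", k, ": admixture source not alive"))
      alive <- unique(c(setdiff(alive, e$derived), e$source1, e$source2))
      if (is.na(e$prop_param))
        v <- c(v, paste0("event ", k, ": admixture without proportion"))
    } else {
      v <- c(v, paste0("event ", k, ": unknown type `", e$type, "`"))
    }
  }
  if (length(alive) != 1)
    v <- c(v, "disconnected: process does not end in a single root population")
  if (!all(s$pops %in% names(s$ne_params)))
    v <- c(v, "missing effective-size parameter for a population")
  if (!is.null(priors)) {
    for (tp in ev$time_param) {
      p <- priors$params[[tp]]
      if (is.null(p)) v <- c(v, paste0("no prior for time `", tp, "`"))
      else if (p$min <= 0) v <- c(v, paste0("time `", tp, "` not strictly positive"))
    }
    for (rp in stats::na.omit(ev$prop_param)) {
      p <- priors$params[[rp]]
      if (is.null(p)) v <- c(v, paste0("no prior for proportion `", rp, "`"))
      else if (p$min <= 0 || p$max >= 1)
        v <- c(v, paste0("degenerate admixture: `", rp,
                         "` must lie strictly in (0, 1)"))
    }
  }
  v
}

#' Draw one parameter set from a prior
#'
#' Samples every parameter independently from its marginal, then enforces
#' ordering constraints by resampling only the violating parameters, up to
#' `max_attempts` rounds.
#'
#' @param s a `scenario`.
#' @param priors a [prior_spec()] covering all of [scenario_params()].
#' @param seed optional integer seed.
#' @param max_attempts resampling rounds before giving up.
#' @return Named numeric vector of parameter values.
#' @export
draw_parameters <- function(s, priors, seed = NULL, max_attempts = 10000) {
  if (!is.null(seed)) set.seed(seed)
  need <- scenario_params(s)
  missing <- setdiff(need, names(priors$params))
  if (length(missing))
    stop("no prior for parameter(s): ", paste(missing, collapse = ", "))
  draw1 <- function(nm) {
    p <- priors$params[[nm]]
    if (p$min == p$max) return(p$min)
    switch(p$dist,
      uniform = stats::runif(1, p$min, p$max),
      loguniform = exp(stats::runif(1, log(p$min), log(p$max)))
    )
  }
  vals <- vapply(need, draw1, 1.0)
  cons <- Filter(function(cn) all(cn %in% need), priors$constraints)
  for (attempt in seq_len(max_attempts)) {
    bad <- character(0)
    for (cn in cons)
      if (!(vals[cn[1]] > vals[cn[2]])) bad <- c(bad, cn[1])
    if (length(bad) == 0) return(vals)
    for (nm in unique(bad)) vals[nm] <- draw1(nm)
  }
  stop("ordering constraints unsatisfied after ", max_attempts, " attempts")
}

div_event <- function(time_param, derived, source) {
  data.frame(time_param = time_param, type = "divergence", derived = derived,
             source1 = source, source2 = NA_character_,
             prop_param = NA_character_, stringsAsFactors = FALSE)
}

adm_event <- function(time_param, derived, sourceA, sourceB, prop_param) {
  data.frame(time_param = time_param, type = "admixture", derived = derived,
             source1 = sourceA, source2 = sourceB, prop_param = prop_param,
             stringsAsFactors = FALSE)
}

ne_for <- function(pops) stats::setNames(paste0("N_", pops), pops)

#' The twelve dissemination scenarios, grouped into four hypotheses
#'
#' Ships the competing divergence/admixture models for the four gene-flow
#' questions on Eurasian grapevine germplasm: (1) origin of the Southern
#' Italian population from the Balkans, (2) the relationship between the
#' Italian and Western/Central European populations, (3) gene flow from
#' Southern Italy to Western/Central Europe via Iberia, and (4) gene flow
#' from the Eastern Mediterranean/Middle-Far East group to Iberia via
#' Northern Africa. Each hypothesis compares three scenarios — two serial
#' divergence orders and either an independent-origin or an admixture
#' alternative. Times satisfy t2 > t1 > 0 (present = 0). Prior bounds are
#' package defaults (the source study does not publish its priors) and can
#' be overridden.
#'
#' @return A named list of four hypotheses; each has `pops`, `scenarios`
#'   (list of 3 [scenario()] objects) and `priors` (list of matching
#'   [default_priors()]).
#' @export
scenario_fixtures <- function() {
  h <- list()

  p1 <- c("BALK", "ITAP_south", "ITAP_north_center")
  h$hypothesis1 <- list(pops = p1, scenarios = list(
    scenario("S1", p1, rbind(
      div_event("t1", "ITAP_north_center", "ITAP_south"),
      div_event("t2", "ITAP_south", "BALK")), ne_for(p1)),
    scenario("S2", p1, rbind(
      div_event("t1", "ITAP_south", "ITAP_north_center"),
      div_event("t2", "ITAP_north_center", "BALK")), ne_for(p1)),
    scenario("S3", p1, rbind(
      div_event("t1", "ITAP_north_center", "BALK"),
      div_event("t2", "ITAP_south", "BALK")), ne_for(p1))
  ))

  p2 <- c("ITAP_south", "ITAP_north_center", "WCEUR")
  h$hypothesis2 <- list(pops = p2, scenarios = list(
    scenario("S4", p2, rbind(
      div_event("t1", "WCEUR", "ITAP_north_center"),
      div_event("t2", "ITAP_north_center", "ITAP_south")), ne_for(p2)),
    scenario("S5", p2, rbind(
      div_event("t1", "ITAP_north_center", "WCEUR"),
      div_event("t2", "WCEUR", "ITAP_south")), ne_for(p2)),
    scenario("S6", p2, rbind(
      adm_event("t1", "ITAP_north_center", "ITAP_south", "WCEUR", "r"),
      div_event("t2", "WCEUR", "ITAP_south")), ne_for(p2))
  ))

  p3 <- c("ITAP_south", "IBER", "WCEUR")
  h$hypothesis3 <- list(pops = p3, scenarios = list(
    scenario("S7", p3, rbind(
      div_event("t1", "WCEUR", "IBER"),
      div_event("t2", "IBER", "ITAP_south")), ne_for(p3)),
    scenario("S8", p3, rbind(
      adm_event("t1", "WCEUR", "ITAP_south", "IBER", "r"),
      div_event("t2", "IBER", "ITAP_south")), ne_for(p3)),
    scenario("S9", p3, rbind(
      div_event("t1", "ITAP_south", "IBER"),
      div_event("t2", "IBER", "WCEUR")), ne_for(p3))
  ))

  p4 <- c("EMR", "MAGH", "IBER")
  h$hypothesis4 <- list(pops = p4, scenarios = list(
    scenario("S10", p4, rbind(
      div_event("t1", "IBER", "MAGH"),
      div_event("t2", "MAGH", "EMR")), ne_for(p4)),
    scenario("S11", p4, rbind(
      adm_event("t1", "IBER", "MAGH", "EMR", "r"),
      div_event("t2", "MAGH", "EMR")), ne_for(p4)),
    scenario("S12", p4, rbind(
      div_event("t1", "EMR", "MAGH"),
      div_event("t2", "MAGH", "IBER")), ne_for(p4))
  ))

  for (nm in names(h))
    h[[nm]]$priors <- lapply(h[[nm]]$scenarios, default_priors)
  h
}

#' Well-separated hypothesis-1 fixture with point parameters
#'
#' The three hypothesis-1 scenarios with degenerate (point) priors chosen so
#' the scenarios are statistically distinguishable from frequency-based
#' summary statistics: all branches at Ne = 1,000 diploids; the deep split
#' at t2 = 600 generations in every scenario; the intermediate split at
#' t1 = 100 for the reference serial order and the independent-origin
#' alternative, and at t = 300 for the reversed serial order. With equal
#' intermediate times and equal branch sizes the two serial orders would be
#' *identical* in law (only the label of the branch carrying the merged
#' lineages differs), so no separation fixture can use them; the staggered
#' time is what makes the fixture well-separated.
#'
#' @return A list with `pops`, `scenarios` and `priors` (point priors), as
#'   in [scenario_fixtures()] entries.
#' @export
separated_hypothesis1 <- function() {
  fx <- scenario_fixtures()$hypothesis1
  ne <- c(N_BALK = 1000, N_ITAP_south = 1000, N_ITAP_north_center = 1000)
  t_by_scenario <- list(
    S1 = c(t1 = 100, t2 = 600),
    S2 = c(t1 = 300, t2 = 600),
    S3 = c(t1 = 100, t2 = 600)
  )
  fx$priors <- lapply(fx$scenarios, function(s)
    point_priors(c(ne, t_by_scenario[[s$id]])))
  fx
}

# ---- config (de)serialization ----------------------------------------------

#' Write or read a scenario + prior configuration file
#'
#' YAML schema: `id`, `pops`, `events` (list of event records), `ne_params`,
#' and optionally `priors` (`params` + `constraints`). Round-trips exactly.
#'
#' @param s a `scenario`.
#' @param priors optional [prior_spec()].
#' @param path file path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns `list(scenario, priors)`.
#' @export
write_scenario_config <- function(s, priors = NULL, path) {
  cfg <- list(
    id = s$id, pops = as.list(s$pops),
    events = lapply(seq_len(nrow(s$events)), function(k) {
      e <- as.list(s$events[k, ])
      e[!vapply(e, is.na, TRUE)]
    }),
    ne_params = as.list(s$ne_params)
  )
  if (!is.null(priors))
    cfg$priors <- list(params = priors$params,
                       constraints = lapply(priors$constraints, as.list))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ev <- do.call(rbind, lapply(cfg$events, function(e) {
    data.frame(
      time_param = e$time_param, type = e$type, derived = e$derived,
      source1 = e$source1,
      source2 = if (is.null(e$source2)) NA_character_ else e$source2,
      prop_param = if (is.null(e$prop_param)) NA_character_ else e$prop_param,
      stringsAsFactors = FALSE)
  }))
  s <- scenario(cfg$id, unlist(cfg$pops), ev,
                stats::setNames(unlist(cfg$ne_params), names(cfg$ne_params)))
  priors <- NULL
  if (!is.null(cfg$priors))
    priors <- prior_spec(cfg$priors$params,
                         lapply(cfg$priors$constraints, unlist))
  list(scenario = s, priors = priors)
}
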