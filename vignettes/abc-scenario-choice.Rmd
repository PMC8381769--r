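---
title: "ABC scenario choice for SNP germplasm panels: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ABC scenario choice for SNP germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vineflow)
```

This vignette is the package's account of its methods: what is being
modelled, which knobs matter, what the synthetic data do and do not emulate,
and where genuinely open design choices were resolved.

## The inference problem

Germplasm collections of clonally propagated crops carry the genetic imprint
of how varieties moved between regions. Frequency-based statistics (Fst, Nei
distance, gene diversity) describe *that* populations differ; they do not by
themselves say *in which order* populations were founded or whether a
population is an admixture of two others. The package addresses the ordering
question with approximate Bayesian computation: competing demographic
scenarios are made explicit, data are simulated under each, and the scenario
whose simulations most resemble the observed panel is preferred — with
explicit error rates and goodness-of-fit checks, because near-twin scenarios
are common in this setting and an unexamined posterior probability is easy to
over-read.

## The demographic model

A `scenario()` is a backward-time event list over named populations. Two
event types exist: a **divergence** at time *t* moves all lineages of a
derived population into a source population (forward in time: the source
founded the derived population at *t*); an **admixture** at time *t* sends
each lineage of the admixed population independently to source A with
probability *r*, else to source B. Every population branch carries its own
diploid effective size Ne, times are in generations (*t*₂ > *t*₁ > 0, present
= 0), and the process must end in a single root. `validate_scenario()`
enforces these structural rules and names the rule broken.

Genotypes are simulated under the structured coalescent: within a branch of
size Ne, each lineage pair coalesces at rate 1/(2 Ne) per generation, with
exact exponential waiting times between events (no generation-by-generation
stepping). Each locus is an independent genealogy carrying a single mutation
placed on a branch with probability proportional to branch length — the
natural model for array SNPs, which are ascertained polymorphisms rather
than sequence. Loci are unlinked; the ABC statistics used are
frequency-based, so within-locus recombination and between-locus linkage
would add cost without adding information. A pooled minor-allele-frequency
condition (default 5%, matching the panel QC filter) is applied inside the
simulation by redrawing the whole locus, so that simulated and observed
panels pass through the same ascertainment. The engine is written in C++
(Rcpp) and driven by R's RNG, which makes every simulation reproducible from
`set.seed()`-style integer seeds.

## Parameters, priors, defaults

The scenario parameters and their shipped priors:

| parameter | meaning | unit | default prior |
|---|---|---|---|
| Ne (per branch) | diploid effective size | individuals | log-uniform [100, 10,000] |
| t₁ | most recent event time | generations | uniform [10, 500] |
| t₂, ... | older event times | generations | uniform [10, 2,000], constrained tₖ₊₁ > tₖ |
| r | admixture proportion | — | uniform [0.05, 0.95] |

These bounds are package defaults, chosen to span the plausible range for
crop germplasm populations (hundreds to thousands of effective individuals;
splits within the last two millennia of generations) while keeping the
ordering constraints satisfiable by resampling; the source study this design
follows does not publish its priors, so ours are deliberately broad and
overridable per scenario (`prior_spec()`, `point_priors()`). Ordering
constraints are enforced by resampling only the violating parameters, which
preserves the marginals of the others.

Other defaults that matter:

* **QC thresholds** — SNP NA rate ≤ 1%, MAF ≥ 5%, sample NA rate ≤ 5%,
  duplicate mismatch cutoff 20%. Filters run SNPs first, then samples, then
  duplicates; the order matters because each stage changes the rates the
  next stage sees. Duplicate removal keeps the first member (input order) of
  each connected component of flagged pairs — a deterministic rule chosen
  because nothing in the data distinguishes original from copy.
* **LD pruning** — windows of 50 SNPs, step 5, VIF threshold 2, the
  conventional independence-pruning triple. The window is SNP-count-based:
  a step quoted in SNPs and a VIF construction only make sense SNP-wise.
* **Rejection tolerance** — 1% of simulations retained; with the default
  100k-scale budgets this leaves enough rows for a stable 9-covariate
  logistic fit. The regression is weighted by the Epanechnikov kernel
  1 − (d/d_max)², the standard choice in regression-ABC, with a 10⁻⁶ ridge
  so complete separation (common when one scenario dominates the retained
  set) cannot crash the fit.
* **Standardization** — statistics are centered and scaled by mean and
  standard deviation over the pooled reference table before distances are
  computed, so the posterior is invariant to affine rescaling of any
  statistic. Zero-variance statistics are dropped with a warning.
* **Infinite Nei distances** (disjoint fixation at every locus) are capped
  at 10.0 before standardization so the summary vector stays finite; in
  practice the cap only binds for degenerate prior draws.

## The selection rule

Scenario choice does not stop at "highest posterior probability". The
selection rule ranks scenarios by logistic-regression posterior probability
and reports, alongside the winner: whether its 95% CI overlaps the
runner-up's, and whether it also minimizes the number of summary statistics
its posterior-predictive distribution fails to reproduce (two-sided tail
probability below 0.05 / 0.01). Ties on probability break by fewer outliers,
then input order. The confidence intervals come from a percentile bootstrap
over the retained simulations (100 resamples by default); the source design
reports 95% CIs without stating a method, and the bootstrap was chosen over
the logistic model's asymptotic covariance because the retained set is small
and the fit is kernel-weighted. Intervals are widened, if necessary, to
contain the point estimate so overlap checks stay coherent.

Parameter adjustment follows the local-linear recipe on the logit scale:
each parameter is mapped by z = ln((θ − a)/(b − θ)) to the real line using
its prior bounds [a, b], a weighted linear regression of z on the
standardized statistics shifts every retained draw to the observed vector,
and the inverse transform guarantees adjusted values remain strictly inside
the prior support — which in turn guarantees the posterior-predictive
simulations never need out-of-bounds parameters.

## Error rates and the twin-scenario problem

`confusion_analysis()` estimates how often the pipeline picks the wrong
scenario: pseudo-observed datasets are simulated under each scenario and
classified by highest posterior probability against a shared reference
table. Type-I error of a scenario is the fraction of its own datasets it
fails to claim; type-II is the fraction of other scenarios' datasets it
wrongly claims. Classification uses the probability ranking alone — the
outlier criterion needs posterior-predictive simulation per pseudo-observed
dataset, a cost that buys nothing for a sensitivity estimate.

One structural fact shapes the test fixtures: two serial-founding scenarios
that differ only in the *order* of the intermediate population are
statistically identical when all branches share one Ne and the same split
times, because relabelling the branch that carries the merged lineages does
not change the genealogy distribution. No method can separate true twins.
The shipped "well-separated" fixture (`separated_hypothesis1()`) therefore
staggers the intermediate split time of the alternative serial order (300 vs
100 generations, all Ne = 1,000, deep split 600) so that the three competing
topologies produce distinct pairwise-differentiation signatures. Under that
fixture, discrimination at the study scale (2,000 simulations/scenario, 500
loci, 30 diploids/population) is essentially perfect, comfortably inside the
20% mean type-I/II design bound. When analysing real panels, scenarios that
are near-twins under the priors will show their nature honestly here — as
chance-level confusion rows.

## What the synthetic panel does and does not emulate

`generate_study()` produces array-like panels with known truth: coalescent
genotypes under a chosen scenario, ascertainment MAF, two independent
Bernoulli layers of missing calls (attributed to SNP and to sample quality),
and appended clone samples with a symmetric per-locus genotype-flip error —
the signature of clonally propagated varieties genotyped twice. It does
**not** emulate: batch-structured missingness, linked loci (so LD-decay
curves on synthetic panels are flat at baseline — the LD machinery is
exercised on constructed fixtures instead), genotype-calling error beyond
the clone-error model, or pedigree structure within populations. Passing
tests on synthetic panels therefore demonstrate the correctness of the
computations and the recoverability of ground truth under the stated model,
not robustness to every artefact of real array data.

## Numerical choices and degenerate inputs

* Fst: the Weir–Cockerham estimator is used for pairs; loci monomorphic
  across a pair carry no information and drop out. A pair identically fixed
  at *every* locus has an undefined estimate; `pairwise_fst()` raises an
  error, while `summary_vector()` maps the situation to 0 (no detectable
  differentiation), which keeps degenerate prior draws inside the reference
  table rather than aborting it. The estimator is slightly negative on
  literally duplicated samples (≈ −1/(2n̄ − 1)); that is a property of the
  estimator, not a bug, and the tests pin it.
* IBD: the method-of-moments solution is truncated to the probability
  simplex, which makes π̂ for unrelated pairs positively biased by roughly
  0.02 at 2,000 SNPs (the price of the [0, 1] guarantee); group-level
  summaries are means of π̂, log-transformed with a 10⁻⁶ floor.
* MDS axes are sign-fixed (largest-magnitude loading positive) so
  coordinates are reproducible across platforms; negative eigenvalues from
  non-Euclidean inputs are dropped with a warning.
* NJ trees clamp negative distance entries to 0; tree construction is
  `ape::nj`, and leaf order does not affect the unrooted topology.
* LD decay distance is read off the curve by linear interpolation between
  consecutive non-empty bin midpoints at the first downward crossing of the
  threshold (default r² = 0.05); if the curve never crosses from above the
  distance is flagged undefined rather than extrapolated.
* The VIF pruner mean-imputes missing dosages inside its regressions only;
  missingness elsewhere is preserved. Equal-VIF ties remove the
  later-indexed locus, so an exact duplicate removes the copy, not the
  original.

## Problem sizes

The shipped analyses and tests run at deliberately modest sizes chosen to
make the statistical properties measurable while keeping a full run on one
CPU in minutes: reference tables of 2,000 simulations per scenario at 500
loci and 30 diploids per population for the discrimination experiment (with
60 pseudo-observed datasets), 1,000 simulations per scenario for the worked
analysis, and a 1,500-locus, 126-sample synthetic panel for the QC and
statistics stages. All are parameters of the corresponding functions;
scaling them up changes cost linearly and precision by the usual √n.

## Known limitations

* Scenarios support splits and point admixtures only — no continuous
  migration, growth or bottleneck phases. Graphs requiring those belong to
  likelihood-based or sequence-scale tools.
* The summary vector is fixed to the diversity/Fst/Nei composition; adding
  statistics is straightforward but changes the meaning of the shipped
  tolerances.
* Posterior probabilities from regression-ABC are only as good as the
  summary statistics are informative; the confusion analysis is the
  package's built-in honesty check and should be run whenever the scenario
  set changes.
* The coalescent engine targets panel-scale data (tens of samples, hundreds
  of loci per dataset, millions of genealogies per analysis); it is not a
  sequence simulator.
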