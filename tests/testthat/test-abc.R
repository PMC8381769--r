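# Small shared reference table for the module tests (3 scenarios, point
# priors, deliberately modest sizes).
abc_fixture <- local({
  fx <- separated_hypothesis1()
  counts <- c(BALK = 10, ITAP_south = 10, ITAP_north_center = 10)
  ref <- build_reference_table(fx$scenarios, fx$priors, counts,
                               n_loci = 150, n_sims_per_scenario = 150,
                               seed = 101)
  list(fx = fx, counts = counts, ref = ref)
})

test_that("summary vectors have the P + 2 C(P,2) composition", {
  s2 <- split_scenario(0)
  g2 <- simulate_dataset(s2, c(N_A = 500, N_B = 500, t1 = 100),
                         c(A = 6, B = 6), 50, seed = 13)
  expect_length(summary_vector(g2, c("A", "B")), 4)

  g3 <- abc_fixture$ref  # any 3-population dataset
  fx <- abc_fixture$fx
  th <- draw_parameters(fx$scenarios[[1]], fx$priors[[1]], seed = 14)
  g <- simulate_dataset(fx$scenarios[[1]], th, abc_fixture$counts, 50,
                        seed = 15)
  sv <- summary_vector(g, fx$pops)
  expect_length(sv, 9)
  expect_equal(names(sv)[1:3], paste0("He_", fx$pops))

  # four populations -> 16 statistics
  g4 <- g
  g4$pop_labels[1:5] <- "EXTRA"
  sv4 <- summary_vector(g4, c(fx$pops, "EXTRA"))
  expect_length(sv4, 16)

  # three identical populations: all pairwise distances collapse to zero
  dos <- matrix(rep(rbinom(60, 2, 0.5), each = 9), nrow = 9)
  gid <- toy_gm(dos, pops = rep(c("X", "Y", "Z"), 3))
  svid <- summary_vector(gid, c("X", "Y", "Z"))
  expect_true(all(abs(svid[4:9]) < 1e-10))
  expect_equal(svid[["He_X"]], svid[["He_Y"]])
})

test_that("reference tables are rectangular and seed-reproducible", {
  ref <- abc_fixture$ref
  expect_equal(nrow(ref$stats), 450)
  expect_equal(as.vector(table(ref$scenario)), rep(150, 3))
  fx <- abc_fixture$fx
  ref2 <- build_reference_table(fx$scenarios, fx$priors, abc_fixture$counts,
                                n_loci = 150, n_sims_per_scenario = 150,
                                seed = 101)
  expect_identical(ref2$stats, ref$stats)
  expect_identical(ref2$params, ref$params)
})

test_that("statistic spread under point priors shrinks like 1/n_loci", {
  fx <- abc_fixture$fx
  s1 <- fx$scenarios[[1]]
  pr1 <- fx$priors[[1]]
  counts <- abc_fixture$counts
  ref_small <- build_reference_table(list(s1), list(pr1), counts,
                                     n_loci = 100, n_sims_per_scenario = 120,
                                     seed = 102)
  ref_big <- build_reference_table(list(s1), list(pr1), counts,
                                   n_loci = 400, n_sims_per_scenario = 120,
                                   seed = 103)
  # Monte-Carlo variance of the mean-over-loci statistics scales ~ 1/n_loci
  v_ratio <- var(ref_small$stats[, "Fst_BALK_ITAP_south"]) /
    var(ref_big$stats[, "Fst_BALK_ITAP_south"])
  expect_gt(v_ratio, 2)
  expect_lt(v_ratio, 8)
})

test_that("rejection retains the brute-force nearest rows", {
  ref <- abc_fixture$ref
  obs <- ref$stats[77, ]
  rej <- abc_reject(ref, obs, tolerance = 0.01)
  expect_equal(length(rej$indices), ceiling(0.01 * 450))
  expect_equal(rej$indices[1], 77)
  expect_equal(rej$distances[1], 0)

  # brute-force oracle: standardize independently and fully sort
  ctr <- colMeans(ref$stats); scl <- apply(ref$stats, 2, sd)
  z <- scale(ref$stats, ctr, scl)
  zo <- (obs - ctr) / scl
  d <- sqrt(colSums((t(z) - zo)^2))
  n_keep <- ceiling(0.20 * 450)
  expect_equal(abc_reject(ref, obs, 0.20)$indices,
               order(d, seq_along(d))[1:n_keep])
})

test_that("model choice: posterior probabilities are coherent", {
  ref <- abc_fixture$ref
  fx <- abc_fixture$fx
  # observed generated under scenario S1
  th <- draw_parameters(fx$scenarios[[1]], fx$priors[[1]], seed = 104)
  g <- simulate_dataset(fx$scenarios[[1]], th, abc_fixture$counts, 150,
                        seed = 105)
  obs <- summary_vector(g, fx$pops)
  mc <- model_choice(ref, obs, tolerance = 0.05, bootstrap_B = 60,
                     seed = 106)
  tab <- mc$table
  expect_equal(sum(tab$pp), 100, tolerance = 0.1)
  expect_true(all(tab$ci_lo <= tab$pp + 1e-9 & tab$pp <= tab$ci_hi + 1e-9))
  expect_true(all(tab$ci_lo >= 0 & tab$ci_hi <= 100))
  expect_equal(tab$scenario[which.max(tab$pp)], "S1")

  # retained rows all from one scenario -> near-certain choice
  ref1 <- ref
  keep <- ref1$scenario == "S1"
  obs1 <- colMeans(ref$stats[keep, ])
  # an observed vector at the S1 centroid with a tolerance small enough to
  # retain only S1 rows
  rej <- abc_reject(ref, obs1, 0.02)
  if (all(ref$scenario[rej$indices] == "S1")) {
    mc1 <- suppressWarnings(model_choice(ref, obs1, 0.02, bootstrap_B = 0))
    expect_gt(mc1$table$pp[mc1$table$scenario == "S1"], 99)
  }

  # shuffled labels destroy the signal: logistic and direct estimates agree
  # loosely (both near uninformative)
  ref_sh <- ref
  set.seed(107)
  ref_sh$scenario <- sample(ref_sh$scenario)
  mc_sh <- model_choice(ref_sh, obs, tolerance = 0.10, bootstrap_B = 0)
  expect_true(all(abs(mc_sh$table$pp - mc_sh$table$direct) < 35))
})

test_that("the selection rule reproduces the reported scenario choices", {
  expected <- c(hypothesis1 = "S1", hypothesis2 = "S6",
                hypothesis3 = "S7", hypothesis4 = "S10")
  expected_pp <- c(hypothesis1 = 74, hypothesis2 = 81,
                   hypothesis3 = 88, hypothesis4 = 75)
  for (h in names(expected)) {
    tab <- reported_model_choice(h)
    sel <- select_best_scenario(tab)
    expect_equal(sel$selected, unname(expected[h]))
    expect_equal(sel$pp, unname(expected_pp[h]))
  }
  # tie on Pp: fewest outliers wins
  tie <- data.frame(scenario = c("X", "Y"), pp = c(60, 60),
                    n_outliers = c(5L, 2L))
  expect_equal(select_best_scenario(tie)$selected, "Y")
})

test_that("parameter adjustment is logit-bounded and exact on linear cases", {
  ref <- abc_fixture$ref
  fx <- abc_fixture$fx
  # priors here are points; use a synthetic table with a uniform prior
  s1 <- fx$scenarios[[1]]
  pr <- prior_spec(list(
    N_BALK = list(dist = "uniform", min = 1000, max = 1000),
    N_ITAP_south = list(dist = "uniform", min = 1000, max = 1000),
    N_ITAP_north_center = list(dist = "uniform", min = 1000, max = 1000),
    t1 = list(dist = "uniform", min = 50, max = 400),
    t2 = list(dist = "uniform", min = 600, max = 600)))
  counts <- abc_fixture$counts
  refu <- build_reference_table(list(s1), list(pr), counts, n_loci = 120,
                                n_sims_per_scenario = 150, seed = 108)
  th <- draw_parameters(s1, fx$priors[[1]], seed = 109)
  g <- simulate_dataset(s1, th, counts, 120, seed = 110)
  obs <- summary_vector(g, fx$pops)
  post <- adjust_parameters(refu, obs, "S1", pr, tolerance = 0.2)
  expect_true(all(post$t1 > 50 & post$t1 < 400))
  expect_true(all(post$t2 == 600))

  # a retained row whose statistics equal the observed vector is unchanged
  obs_row <- refu$stats[33, ]
  post2 <- adjust_parameters(refu, obs_row, "S1", pr, tolerance = 0.2)
  rej <- abc_reject(refu, obs_row, 0.2)
  pos <- which(rej$indices == 33)
  expect_equal(post2$t1[pos], refu$params$t1[33], tolerance = 1e-6)

  # exact linear relationship: adjusted draws collapse to the implied value
  refl <- refu
  zstats <- scale(refu$stats)
  # construct t1 so its logit is an exact linear function of the statistics
  zt <- 0.3 * zstats[, 1] - 0.2 * zstats[, 5] + 0.1
  refl$params$t1 <- (50 + 400 * exp(zt)) / (1 + exp(zt))
  postl <- adjust_parameters(refl, obs_row, "S1", pr, tolerance = 0.5)
  expect_lt(diff(range(postl$t1)), 1e-6)
})

test_that("confusion analysis accounts consistently and respects symmetry", {
  fx <- abc_fixture$fx
  counts <- abc_fixture$counts
  # three *identical* generative models: classification is pure chance
  s_same <- lapply(c("C1", "C2", "C3"), function(id) {
    s <- fx$scenarios[[1]]
    s$id <- id
    s
  })
  pr_same <- rep(list(fx$priors[[1]]), 3)
  rep_same <- confusion_analysis(s_same, pr_same, counts, n_loci = 60,
                                 n_sims_per_scenario = 100,
                                 n_pods_per_scenario = 12, tolerance = 0.05,
                                 seed = 111)
  # overall accuracy within binomial 99% bounds around 1/3
  n_tot <- sum(rep_same$confusion)
  bounds <- qbinom(c(0.005, 0.995), n_tot, 1 / 3) / n_tot
  expect_gte(rep_same$performance, bounds[1])
  expect_lte(rep_same$performance, bounds[2])

  # accounting identity: performance = 1 - pod-weighted mean type-I error
  n_pods <- rowSums(rep_same$confusion)
  expect_equal(rep_same$performance,
               1 - sum(rep_same$type1 * n_pods) / sum(n_pods),
               tolerance = 1e-12)
  expect_true(all(rep_same$type1 >= 0 & rep_same$type1 <= 1))
  expect_true(all(rep_same$type2 >= 0 & rep_same$type2 <= 1))
})

test_that("model checking flags gross misfit and passes self-fit", {
  fx <- abc_fixture$fx
  ref <- abc_fixture$ref
  counts <- abc_fixture$counts
  s1 <- fx$scenarios[[1]]
  th1 <- draw_parameters(s1, fx$priors[[1]], seed = 112)
  post <- as.data.frame(as.list(th1))[rep(1, 50), ]

  # observed drawn from the fitted scenario itself: few outliers
  g_ok <- simulate_dataset(s1, th1, counts, 150, seed = 113)
  obs_ok <- summary_vector(g_ok, fx$pops)
  chk_ok <- model_check(s1, post, counts, 150, n_ppc = 80, obs_ok, ref,
                        seed = 114)
  expect_lte(chk_ok$outliers_p05, 3)
  expect_true(all(chk_ok$tail_prob >= 0 & chk_ok$tail_prob <= 1))
  expect_lte(chk_ok$outliers_p01, chk_ok$outliers_p05)

  # observed from a grossly different model (deep splits, tiny Ne)
  s3 <- fx$scenarios[[3]]
  g_bad <- simulate_dataset(
    s3, c(N_BALK = 150, N_ITAP_south = 150, N_ITAP_north_center = 150,
          t1 = 2000, t2 = 4000), counts, 150, seed = 115)
  obs_bad <- summary_vector(g_bad, fx$pops)
  chk_bad <- model_check(s1, post, counts, 150, n_ppc = 80, obs_bad, ref,
                         seed = 116)
  expect_gte(chk_bad$outliers_p05, 4)
  expect_equal(dim(chk_bad$pca$predictive), c(80L, 2L))
})
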