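test_that("cohort config validates its invariants", {
  expect_error(cohort_config(n_pairs = 1), "n_pairs")
  expect_error(cohort_config(class_fractions = c(error_only = 0.5, genetic = 0.5,
                                                 stochastic = 0.5, mixed = -0.5)),
               "sum to 1")
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(sigma_meas = -1), "scales")
})

test_that("twin cohorts have the promised shape and are seed-reproducible", {
  ch <- tiny_cohort()
  expect_equal(dim(ch$beta), c(60, 12))
  expect_true(all(ch$beta > 0 & ch$beta < 1))
  expect_equal(nrow(ch$sheet), 12)
  expect_equal(as.vector(table(ch$truth$class)[c("error_only", "genetic",
                                                 "stochastic", "mixed")]),
               c(42, 12, 3, 3))
  ch2 <- tiny_cohort()
  expect_identical(ch$beta, ch2$beta)
  ch3 <- tiny_cohort(seed = 8)
  expect_false(identical(ch$beta, ch3$beta))
})

test_that("noise-free genetic cohorts give exactly zero co-twin differences", {
  ch <- simulate_twin_cohort(cohort_config(
    n_pairs = 10, n_cpgs = 20, sigma_meas = 0,
    class_fractions = c(error_only = 0, genetic = 1, stochastic = 0, mixed = 0)))
  twin1 <- ch$beta[, seq(1, 20, 2)]
  twin2 <- ch$beta[, seq(2, 20, 2)]
  expect_identical(twin1, structure(twin2, dimnames = dimnames(twin1)))
})

test_that("stochastic CpGs give exchangeable twin and unrelated differences", {
  ch <- simulate_twin_cohort(cohort_config(
    n_pairs = 2500, n_cpgs = 2, sigma_meas = 0,
    class_fractions = c(error_only = 0, genetic = 0, stochastic = 1, mixed = 0),
    seed = 42))
  d <- pair_abs_diffs(ch$beta[1, ], ch$sheet,
                      unrelated_mode("subsample", k = 10000, seed = 3))
  ks <- suppressWarnings(stats::ks.test(d$twin_diffs, d$unrelated_diffs))
  expect_gt(ks$p.value, 0.01)
})

test_that("error-only observed spread matches the logit delta-method prediction", {
  ch <- simulate_twin_cohort(cohort_config(seed = 1))
  err <- ch$truth$class == "error_only" &
    ch$truth$baseline > 0.45 & ch$truth$baseline < 0.55
  sds <- apply(ch$beta[err, , drop = FALSE], 1, sd)
  # dbeta/dlogit = 0.25 at beta = 0.5, so sd ~ 0.25 * sigma_meas = 0.03
  expect_lt(abs(mean(sds) - 0.03), 0.005)
})

test_that("genetic per-allele effects are recoverable without bias", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 200, n_cpgs = 400,
    class_fractions = c(error_only = 0, genetic = 1, stochastic = 0, mixed = 0),
    baseline_range = c(0.2, 0.4), effect_range = c(0.1, 0.2), seed = 11))
  g <- attr(ch$beta, "genotypes")[, rep(seq_len(200), each = 2)]
  bias <- vapply(seq_len(nrow(ch$beta)), function(i)
    unname(coef(lm(ch$beta[i, ] ~ g[i, ]))[2]) - ch$truth$effect[i], numeric(1))
  expect_lt(abs(mean(bias)), 0.01)
})

test_that("technical replicates without noise are bit-identical", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 3, n_cpgs = 10,
                                           sigma_meas = 0, seed = 2))
  rep <- simulate_replicates(ch$beta, ch$sheet, ch$truth, "technical", k = 2)
  expect_identical(unname(rep$beta[, 1]), unname(rep$beta[, 2]))
  expect_equal(rep$sheet$replicate_id[1:2], 1:2)
})

test_that("longitudinal replicates with no drift recover high ICC for stochastic CpGs", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 60, n_cpgs = 100,
    class_fractions = c(error_only = 0, genetic = 0, stochastic = 1, mixed = 0),
    sigma_stoch = 0.5, sigma_meas = 0.1, seed = 3))
  rep <- simulate_replicates(ch$beta, ch$sheet, ch$truth, "longitudinal",
                             k = 2, sigma_time = 0, seed = 4)
  v <- probe_variability(rep$beta, rep$sheet)
  # variance-ratio target: 0.5^2 / (0.5^2 + 0.1^2) = 0.96 on the logit scale
  expect_gt(median(v$icc), 0.9)
})

test_that("batch structure dominates genetic probes under a large chip shift", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 6, n_cpgs = 100,
    class_fractions = c(error_only = 0, genetic = 1, stochastic = 0, mixed = 0),
    maf_range = c(0.1, 0.2), effect_range = c(0.1, 0.15), seed = 99))
  rep <- simulate_replicates(ch$beta, ch$sheet, ch$truth, "technical", k = 2,
                             seed = 100, n_batches = 2, batch_shift = 0.5)
  pc1 <- prcomp(t(rep$beta))$x[, 1]
  by_batch <- split(pc1, rep$sheet$batch)
  expect_true(max(by_batch[[1]]) < min(by_batch[[2]]) ||
                max(by_batch[[2]]) < min(by_batch[[1]]))
})

test_that("replicate simulation rejects bad inputs", {
  ch <- tiny_cohort()
  expect_error(simulate_replicates(ch$beta, ch$sheet, ch$truth, "weekly"))
  bare <- ch$beta
  attr(bare, "true_beta") <- NULL
  expect_error(simulate_replicates(bare, ch$sheet, ch$truth, "technical"),
               "true values")
  expect_error(simulate_replicates(ch$beta, ch$sheet, ch$truth, "technical",
                                   k = 1), "k must be")
})

test_that("aging cohort nulls reject at the nominal rate and drift is heteroscedastic", {
  ac <- simulate_aging_cohort(200, n_cpgs = c(clock = 0, drift = 0, neither = 2000),
                              clock_slope = 0, drift_rate = 0, seed = 9)
  cl <- classify_aging(ac$beta, ac$sheet)
  expect_lt(abs(mean(cl$results$p_assoc < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(cl$results$p_het < 0.05) - 0.05), 0.02)

  ac2 <- simulate_aging_cohort(300, n_cpgs = c(clock = 0, drift = 150, neither = 0),
                               clock_slope = 0, drift_rate = 0.01, seed = 10)
  cl2 <- classify_aging(ac2$beta, ac2$sheet)
  # pure variance growth: the White test must out-reject the mean-level test
  expect_gt(mean(cl2$results$p_het < 0.05), mean(cl2$results$p_assoc < 0.05))
})

test_that("aging cohort preconditions hold", {
  expect_error(simulate_aging_cohort(0), "n must be")
  expect_error(simulate_aging_cohort(50, age_range = c(40, 40)), "width")
})

test_that("WGBS simulation respects count invariants and the region error", {
  sim <- simulate_wgbs_pair(wgbs_sim_config(n_sites = 2000, seed = 3))
  for (tw in list(sim$twin1, sim$twin2)) {
    expect_true(all(tw$count_methylated >= 0 &
                      tw$count_methylated <= tw$count_total))
    expect_true(all(tw$beta >= 0 & tw$beta <= 1))
    expect_false(is.unsorted(tw$pos))
  }
  expect_error(wgbs_sim_config(region = c(5e6, 2e7)), "region")
  expect_error(wgbs_sim_config(mean_coverage = 0), "mean_coverage")
  sim2 <- simulate_wgbs_pair(wgbs_sim_config(n_sites = 2000, seed = 3))
  expect_identical(sim$twin1, sim2$twin1)
})

test_that("strand-artifact injection removes the expected number of sites", {
  # high coverage + strongly bimodal betas make chance strand discordance
  # negligible, so removals count the injected artifacts
  cfg <- wgbs_sim_config(n_sites = 50000, mean_coverage = 300,
                         coverage_dispersion = 10, beta_shape = c(0.1, 0.1),
                         frac_strand_artifact = 0.01,
                         frac_discordant_in_region = 0, frac_blacklist = 0,
                         seed = 21)
  sim <- simulate_wgbs_pair(cfg)
  pp <- preprocess_wgbs(sim$twin1, sim$twin2)
  removed <- pp$audit$strand_discordant[1]
  expect_lt(abs(removed - 500), 3 * sqrt(500))
})
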