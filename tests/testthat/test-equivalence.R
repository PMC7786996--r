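test_that("pair construction enumerates twin and unrelated pairs", {
  sheet <- toy_sheet(2)
  x <- c(0.1, 0.2, 0.4, 0.8)
  names(x) <- sheet$sample_id
  d <- pair_abs_diffs(x, sheet)
  expect_length(d$twin_diffs, 2)
  expect_length(d$unrelated_diffs, 4)   # C(4,2) - 2 co-twin pairs
  expect_equal(sort(unname(d$twin_diffs)), c(0.1, 0.4))
  expect_equal(sort(d$unrelated_diffs), c(0.2, 0.3, 0.6, 0.7))

  xc <- rep(0.5, 4); names(xc) <- sheet$sample_id
  dc <- pair_abs_diffs(xc, sheet)
  expect_true(all(dc$twin_diffs == 0) && all(dc$unrelated_diffs == 0))

  bad <- sheet; bad$family_id[4] <- "F03"
  expect_error(pair_abs_diffs(x, bad), "exactly 2")
})

test_that("disjoint matchings pair every individual once, never with a co-twin", {
  sheet <- toy_sheet(3)
  x <- runif(6); names(x) <- sheet$sample_id
  for (s in 1:20) {
    d <- pair_design(sheet$sample_id, sheet, unrelated_mode("disjoint", seed = s))
    used <- c(d$un_i, d$un_j)
    expect_length(d$un_i, 3)
    expect_equal(sort(used), 1:6)
    fam <- sheet$family_id
    expect_true(all(fam[d$un_i] != fam[d$un_j]))
  }
})

test_that("subsampling draws the requested number of distinct unrelated pairs", {
  sheet <- toy_sheet(5)
  d <- pair_design(sheet$sample_id, sheet, unrelated_mode("subsample", k = 7, seed = 2))
  expect_length(d$un_i, 7)
  expect_error(pair_design(sheet$sample_id, sheet,
                           unrelated_mode("subsample", k = 1e6, seed = 2)),
               "exceeds")
})

test_that("the Yuen TOST matches Welch exactly at zero trimming", {
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    eps <- runif(1, 0.05, 1)
    got <- yuen_tost(x, y, eps, trim = 0)
    ref <- welch_tost(x, y, eps)
    expect_equal(got$delta_hat, ref$delta, tolerance = 1e-10)
    expect_equal(got$se, ref$se, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p_lower, ref$p_lower, tolerance = 1e-10)
    expect_equal(got$p_upper, ref$p_upper, tolerance = 1e-10)
  }
})

test_that("TOST p-values behave under symmetry, degeneracy and growing margins", {
  set.seed(32)
  x <- rnorm(50, 0, 0.01)
  got <- yuen_tost(x, x, epsilon = 0.5)
  expect_equal(got$delta_hat, 0)
  expect_lt(got$p_equiv, 1e-10)

  # swapping the samples flips delta but leaves the equivalence p unchanged
  y <- rnorm(40, 0.05, 0.02)
  a <- yuen_tost(x, y, 0.1); b <- yuen_tost(y, x, 0.1)
  expect_equal(a$p_equiv, b$p_equiv, tolerance = 1e-12)
  expect_equal(a$delta_hat, -b$delta_hat)

  # p_equiv is non-increasing in epsilon
  ps <- vapply(seq(0.02, 0.4, by = 0.02),
               function(e) yuen_tost(x, y, e)$p_equiv, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # zero spread: equivalence by convention when the difference is inside
  z1 <- rep(0.2, 10); z2 <- rep(0.25, 10)
  expect_equal(yuen_tost(z1, z2, 0.1)$p_equiv, 0)
  expect_equal(yuen_tost(z1, z2, 0.01)$p_equiv, 1)
  expect_true(yuen_tost(z1, z2, 0.1)$degenerate)

  expect_error(yuen_tost(x[1:3], y, 0.1), "length >= 5")
  expect_error(yuen_tost(x, y, -1), "epsilon")
})

test_that("epsilon calibration is the interpolated quantile of twin means", {
  expect_equal(calibrate_epsilon(rep(0.03, 7), 0.25), 0.03)
  expect_equal(calibrate_epsilon(seq(0.01, 0.10, by = 0.01), 0.5), 0.055)
  expect_error(calibrate_epsilon(rep(0, 5)), "not positive")
  expect_error(calibrate_epsilon(numeric(0)), "empty")
  expect_error(calibrate_epsilon(0.05, q = 1.5), "q must")
})

test_that("discovery on a small cohort gates, tests and intersects branches", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 30, n_cpgs = 200, seed = 17))
  fit <- discover_evcpgs(ch$beta, ch$sheet)
  expect_s3_class(fit, "evcpg_fit")
  gate <- fit$gate[[1]]
  err <- ch$truth$probe_id[ch$truth$class == "error_only"]
  expect_equal(sum(gate$pass[gate$probe_id %in% err]), 0)
  # subset chain: evCpGs within significant within tested
  expect_true(all(fit$evcpgs %in% fit$significant[[1]]))
  expect_true(all(fit$significant[[1]] %in% fit$results[[1]]$probe_id))
  expect_true(all(fit$results[[1]]$p_equiv ==
                    pmax(fit$results[[1]]$p_lower, fit$results[[1]]$p_upper)))

  # three identical branches intersect to the single-branch result
  fit3 <- discover_evcpgs(list(a = ch$beta, b = ch$beta, c = ch$beta), ch$sheet)
  expect_identical(sort(fit3$evcpgs), sort(fit$evcpgs))
  expect_error(discover_evcpgs(list(ch$beta, ch$beta[-1, ]), ch$sheet),
               "share probe")
})

test_that("print, summary and plot methods run on a fit", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 20, n_cpgs = 80, seed = 19))
  fit <- discover_evcpgs(ch$beta, ch$sheet)
  expect_output(print(fit), "evCpG discovery fit")
  s <- summary(fit)
  expect_equal(nrow(s$branches), 1)
  expect_output(print(s), "intersection")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("pure-genetic CpGs are directionally non-equivalent and rejected", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 150, n_cpgs = 150,
    class_fractions = c(error_only = 0, genetic = 1, stochastic = 0, mixed = 0),
    maf_range = c(0.3, 0.3), effect_range = c(0.15, 0.15), seed = 23))
  fit <- discover_evcpgs(ch$beta, ch$sheet)
  res <- fit$results[[1]]
  eps <- fit$epsilon[[1]]
  # unrelated trimmed mean exceeds the twin mean by at least the margin
  expect_gt(mean(res$tm_unrel - res$tm_twin >= eps), 0.95)
  expect_gte(mean(!res$significant), 0.99)
})

test_that("twin concordance is 1 for identical co-twins and ~0 for independent ones", {
  sheet <- toy_sheet(400)
  set.seed(25)
  a <- runif(400, 0.2, 0.8)
  ident <- rep(a, each = 2)
  indep <- runif(800, 0.2, 0.8)
  beta <- rbind(ident = ident, indep = indep, const = rep(0.5, 800))
  colnames(beta) <- sheet$sample_id
  tc <- twin_concordance(beta, sheet)
  expect_equal(tc$concordance[1], 1, tolerance = 1e-12)
  expect_lt(abs(tc$concordance[2]), 0.1)
  expect_equal(tc$concordance[3], 0)
  expect_true(tc$flag[3])
  expect_equal(tc$range[3], 0)
  expect_gt(tc$range[1], 0)
})

test_that("independence check reports bounded agreement and needs enough pairs", {
  ch <- simulate_twin_cohort(cohort_config(n_pairs = 40, n_cpgs = 150, seed = 27))
  ic <- independence_check(ch$beta, ch$sheet, n_resamples = 5, seed = 100)
  expect_true(all(ic$per_cpg$agreement >= 0 & ic$per_cpg$agreement <= 1))
  expect_true(is.finite(ic$overall_agreement))
  sheet2 <- toy_sheet(2)
  beta2 <- matrix(runif(40), 10, 4,
                  dimnames = list(paste0("p", 1:10), sheet2$sample_id))
  expect_error(independence_check(beta2, sheet2), "at least 10")
})


test_that("all-pairs decisions are stable under independent disjoint pairings", {
  ch <- simulate_twin_cohort(cohort_config(seed = 1))
  ic <- independence_check(ch$beta, ch$sheet, n_resamples = 25, seed = 500)
  expect_gte(ic$evcpg_agreement, 0.9)
  expect_gte(ic$overall_agreement, 0.9)
})
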