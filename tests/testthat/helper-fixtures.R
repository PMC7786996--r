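# Small cohort and manifest factories shared across test files.

tiny_cohort <- function(n_pairs = 6, n_cpgs = 60, seed = 7, ...) {
  simulate_twin_cohort(cohort_config(n_pairs = n_pairs, n_cpgs = n_cpgs,
                                     seed = seed, ...))
}

# Sample sheet for hand-built beta matrices: one sample per individual,
# two individuals per family.
toy_sheet <- function(n_pairs) {
  fam <- sprintf("F%02d", rep(seq_len(n_pairs), each = 2))
  id <- paste0(fam, "_T", rep(1:2, n_pairs))
  data.frame(sample_id = id, individual_id = id, family_id = fam,
             stringsAsFactors = FALSE)
}

# Exhaustive one-sided (greater) Fisher p by summing hypergeometric terms
# over all tables at least as extreme -- independent of fisher.test.
enum_fisher_greater <- function(a, b, c, d) {
  m1 <- a + b; n1 <- c + d; k <- a + c
  xs <- a:min(m1, k)
  sum(choose(m1, xs) * choose(n1, k - xs)) / choose(m1 + n1, k)
}

# Adjusted Rand index straight from the contingency-table formula.
manual_ari <- function(x, y) {
  tab <- table(x, y)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(x), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Welch two-sample t machinery, the trim = 0 oracle for the Yuen TOST.
welch_tost <- function(x, y, epsilon) {
  d1 <- stats::var(x) / length(x); d2 <- stats::var(y) / length(y)
  se <- sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (length(x) - 1) + d2^2 / (length(y) - 1))
  delta <- mean(x) - mean(y)
  list(delta = delta, se = se, df = df,
       p_lower = 1 - stats::pt((delta + epsilon) / se, df),
       p_upper = stats::pt((delta - epsilon) / se, df))
}
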