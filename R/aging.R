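#' Cross-sectional age association (epigenetic clock) for one probe
#'
#' Ordinary least squares of beta on age with sex as a covariate; `p_assoc`
#' is the two-sided t test on the age coefficient.
#'
#' @param beta_row Numeric vector of betas.
#' @param age Ages in years (non-constant).
#' @param sex Binary/two-level vector (factor, character or 0/1).
#' @return A list with `slope` (beta per year), `p_assoc` and `residuals`.
#' @export
clock_regression <- function(beta_row, age, sex) {
  n <- length(beta_row)
  if (n < 10) stop_("need at least 10 samples")
  if (stats::var(age) == 0) stop_("age is constant")
  sexn <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  fit <- stats::lm(beta_row ~ age + sexn)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["age", "Estimate"]),
       p_assoc = unname(cf["age", "Pr(>|t|)"]),
       residuals = unname(stats::residuals(fit)))
}

#' White heteroscedasticity test with a quadratic age term
#'
#' Auxiliary OLS of the squared residuals on age and age^2; the Lagrange
#' multiplier statistic is `n * R^2` of the auxiliary fit, referred to a
#' chi-square with 2 degrees of freedom. The quadratic term is what
#' distinguishes this from a plain Breusch-Pagan test and gives power
#' against variance that grows with age (epigenetic drift). Sex enters the
#' mean model only, not the variance model.
#'
#' @param residuals Residuals from [clock_regression()].
#' @param age Ages in years, aligned with `residuals`.
#' @return A list with `lm_stat`, `p_het` and `flag` (`TRUE` when the
#'   residual variance is zero, in which case `p_het = 1` by convention).
#' @export
white_heteroscedasticity_test <- function(residuals, age) {
  n <- length(residuals)
  if (n < 10) stop_("need at least 10 samples")
  if (length(age) != n) stop_("age must align with residuals")
  u2 <- residuals^2
  if (all(u2 == 0) || stats::var(u2) == 0)
    return(list(lm_stat = 0, p_het = 1, flag = TRUE))
  aux <- stats::lm(u2 ~ age + I(age^2))
  r2 <- summary(aux)$r.squared
  lm_stat <- n * r2
  list(lm_stat = lm_stat, p_het = stats::pchisq(lm_stat, df = 2, lower.tail = FALSE),
       flag = FALSE)
}

#' Clock/drift classification of probes
#'
#' Runs the clock regression and White test per probe and classifies each as
#' `clock` (only the age association significant after correction), `drift`
#' (only the heteroscedasticity), `both`, or `neither`. Correction is
#' Bonferroni across the supplied probe set, applied separately to each test
#' family.
#'
#' @param beta Probes x samples matrix.
#' @param sheet Sample sheet with `age` and `sex`.
#' @param alpha Family-wise level.
#' @param correction Only `"bonferroni"`.
#' @return A list with `results` (probe_id, slope, p_assoc, lm_stat, p_het,
#'   class) and `counts` (table with percentages).
#' @export
classify_aging <- function(beta, sheet, alpha = 0.05, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  m <- nrow(beta)
  rows <- lapply(seq_len(m), function(i) {
    cr <- clock_regression(beta[i, ], sheet$age, sheet$sex)
    wt <- white_heteroscedasticity_test(cr$residuals, sheet$age)
    data.frame(probe_id = rownames(beta)[i], slope = cr$slope,
               p_assoc = cr$p_assoc, lm_stat = wt$lm_stat, p_het = wt$p_het,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  thr <- alpha / m
  sig_c <- res$p_assoc < thr
  sig_d <- res$p_het < thr
  res$class <- ifelse(sig_c & sig_d, "both",
                      ifelse(sig_c, "clock", ifelse(sig_d, "drift", "neither")))
  counts <- table(factor(res$class, levels = c("clock", "drift", "both", "neither")))
  list(results = res,
       counts = data.frame(class = names(counts), n = as.integer(counts),
                           pct = round(100 * as.integer(counts) / m, 1),
                           stringsAsFactors = FALSE))
}
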