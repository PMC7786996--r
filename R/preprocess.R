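#' Variability-gate parameters
#'
#' Probes whose inter-quartile range (IQR) or intra-class correlation (ICC)
#' falls below these cut-offs are excluded from discovery, since CpGs with no
#' biological variation show equivalent co-twin and inter-individual spread
#' for the trivial reason that both are measurement error. The IQR default is
#' the spread expected from measurement error alone at a mid-methylated CpG
#' (see [expected_error_iqr()]).
#'
#' @param iqr_min Minimum IQR in beta-value units.
#' @param icc_min Minimum ICC.
#' @param alpha Significance level carried to downstream tests.
#' @return An object of class `qc_gate_params`.
#' @export
qc_gate_params <- function(iqr_min = 0.07, icc_min = 0.37, alpha = 0.05) {
  if (iqr_min < 0 || iqr_min > 1 || icc_min < 0 || icc_min > 1)
    stop_("iqr_min and icc_min must lie in [0, 1]")
  structure(list(iqr_min = iqr_min, icc_min = icc_min, alpha = alpha),
            class = "qc_gate_params")
}

# Fixed attribution order for probes carrying several flags.
FLAG_ORDER <- c("low_quality", "snp", "cross_reactive", "chrX", "chrY")

#' Remove flagged probes
#'
#' Drops beta-matrix rows whose manifest entry carries any of the requested
#' exclusion flags (low-quality, SNP-containing, cross-reactive, X/Y
#' chromosomal). A probe with several flags is removed once and attributed to
#' the first flag in the fixed order low_quality, snp, cross_reactive, chrX,
#' chrY.
#'
#' @param beta Probes x samples matrix.
#' @param manifest Data frame with `probe_id` and a `flags` list-column or
#'   comma-separated character column (see [read_probe_manifest()]).
#' @param drop_flags Flags to act on (default: all five).
#' @return A list with the filtered `beta` and `removed`, a named count per
#'   flag.
#' @export
filter_probes <- function(beta, manifest, drop_flags = FLAG_ORDER) {
  drop_flags <- match.arg(drop_flags, FLAG_ORDER, several.ok = TRUE)
  miss <- setdiff(rownames(beta), manifest$probe_id)
  if (length(miss))
    stop_("probes absent from manifest: ", paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  flags <- manifest$flags
  if (!is.list(flags)) flags <- strsplit(ifelse(is.na(flags), "", flags), ",", fixed = TRUE)
  flags <- lapply(flags, trimws)
  names(flags) <- manifest$probe_id
  attribute <- vapply(flags[rownames(beta)], function(f) {
    hit <- FLAG_ORDER[FLAG_ORDER %in% f & FLAG_ORDER %in% drop_flags]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  removed <- table(factor(attribute, levels = drop_flags))
  list(beta = beta[is.na(attribute), , drop = FALSE],
       removed = stats::setNames(as.integer(removed), drop_flags))
}

# One-way random-effects ANOVA sums of squares, vectorised across probes.
# Groups are individuals, observations are technical replicates.
icc_oneway <- function(beta, group) {
  group <- as.factor(group)
  a <- nlevels(group)
  n_i <- as.integer(table(group))
  N <- sum(n_i)
  G <- t(stats::model.matrix(~ group - 1))        # a x N indicator
  sums <- beta %*% t(G)                           # probe x group sums
  means <- sweep(sums, 2, n_i, `/`)
  grand <- rowSums(beta) / N
  ssb <- rowSums(sweep(sweep(means, 1, grand, `-`)^2, 2, n_i, `*`))
  sst <- rowSums(sweep(beta, 1, grand, `-`)^2)
  ssw <- sst - ssb
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  # Unbalanced-design average group size.
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

#' Per-probe variability: IQR and replicate ICC
#'
#' IQR is `q0.75 - q0.25` (linear-interpolation quantiles) across one sample
#' per individual -- the first replicate in sheet order -- so replicated
#' individuals are not double counted. When at least two individuals carry at
#' least two technical replicates, the one-way random-effects ICC(1),
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with individuals as groups, is computed
#' per probe; negative estimates are reported as-is. Without replicates the
#' `icc` column is `NA` and gating falls back to a user-supplied ICC table.
#'
#' @param beta Probes x samples matrix.
#' @param sheet Sample sheet with `sample_id` and `individual_id`.
#' @return Data frame with `probe_id`, `iqr`, `icc`.
#' @export
probe_variability <- function(beta, sheet) {
  if (ncol(beta) < 4) stop_("fewer than 4 samples")
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop_("samples missing from sheet")
  first <- !duplicated(sheet$individual_id)
  iqr <- apply(beta[, first, drop = FALSE], 1, function(x)
    diff(quantile7(x, c(0.25, 0.75))))
  reps_per_ind <- table(sheet$individual_id)
  icc <- if (sum(reps_per_ind >= 2) >= 2) {
    keep <- sheet$individual_id %in% names(reps_per_ind[reps_per_ind >= 2])
    icc_oneway(beta[, keep, drop = FALSE], sheet$individual_id[keep])
  } else rep(NA_real_, nrow(beta))
  data.frame(probe_id = rownames(beta), iqr = unname(iqr), icc = unname(icc),
             stringsAsFactors = FALSE)
}

#' IQR expected from measurement error alone
#'
#' Fits beta-distribution shape parameters by the method of moments,
#' `a = mean * (mean (1 - mean) / sd^2 - 1)` and `b = (1 - mean) * (...)`,
#' and returns the inter-quartile range of Beta(a, b). At mean 0.5 and sd
#' 0.05 this is 0.07 (2 dp) -- the default variability gate: probes whose
#' observed IQR does not exceed what measurement error alone would produce
#' carry no usable biological signal.
#'
#' @param mean Beta-value mean in (0, 1).
#' @param sd Beta-value standard deviation; `sd^2 < mean * (1 - mean)`.
#' @return The IQR `qbeta(0.75) - qbeta(0.25)` of the fitted distribution.
#' @export
expected_error_iqr <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop_("mean must lie in (0, 1)")
  if (sd <= 0) stop_("sd must be > 0")
  if (sd^2 >= mean * (1 - mean))
    stop_("sd^2 must be < mean * (1 - mean): no beta distribution has these moments")
  nu <- mean * (1 - mean) / sd^2 - 1
  a <- mean * nu
  b <- (1 - mean) * nu
  stats::qbeta(0.75, a, b) - stats::qbeta(0.25, a, b)
}

#' Residualise beta values on sample covariates
#'
#' Per probe, ordinary least squares of beta on the covariates (with
#' intercept); the output is residual plus the probe mean, clamped to
#' \[0, 1\]. A generic stand-in for batch and cell-composition correction.
#'
#' @param beta Probes x samples matrix.
#' @param covariates Numeric data frame, one row per sample in column order
#'   of `beta`; no missing values.
#' @return Matrix of the same shape as `beta`.
#' @export
residualize_covariates <- function(beta, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(beta))
    stop_("covariate rows must align to beta columns")
  if (anyNA(covariates)) stop_("covariates contain missing values")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_("rank-deficient covariate design; collinear columns: ",
          paste(bad, collapse = ", "))
  }
  resid <- t(qr.resid(qr_x, t(beta)))
  out <- pmin(pmax(resid + rowMeans(beta), 0), 1)
  dimnames(out) <- dimnames(beta)
  out
}
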