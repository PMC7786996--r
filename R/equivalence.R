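#' Unrelated-pair construction mode
#'
#' Co-twin absolute differences are compared against differences over pairs
#' of individuals from *different* families. `"all"` uses every such
#' cross-family pair (both co-twins participate; heavily dependent but
#' maximally informative, as in the discovery design); `"subsample"` draws
#' `k` of those pairs without replacement; `"disjoint"` draws a random
#' perfect matching in which each individual appears in at most one pair and
#' never with its co-twin (independent pairs, used by
#' [independence_check()]).
#'
#' @param type One of `"all"`, `"subsample"`, `"disjoint"`.
#' @param k Number of pairs for `"subsample"`.
#' @param seed Integer seed for the stochastic modes.
#' @return An object of class `unrelated_mode`.
#' @export
unrelated_mode <- function(type = c("all", "subsample", "disjoint"),
                           k = NULL, seed = 1) {
  type <- match.arg(type)
  if (type == "subsample" && (!is_count(k) || k < 1))
    stop_("subsample mode requires a positive integer k")
  structure(list(type = type, k = k, seed = as.integer(seed)),
            class = "unrelated_mode")
}

#' Discovery configuration
#'
#' @param trim Trimming proportion gamma for the Yuen test, in \[0, 0.45\].
#' @param epsilon Fixed equivalence margin in beta units, or `NULL` to
#'   calibrate it from the data.
#' @param epsilon_q Quantile of the per-CpG trimmed twin-difference means used
#'   when calibrating epsilon (default: the median).
#' @param alpha Family-wise significance level.
#' @param correction Multiple-testing correction; only `"bonferroni"` is
#'   built in, with `m` = the per-branch tested-CpG count.
#' @param mode An [unrelated_mode()].
#' @return An object of class `discovery_config`.
#' @export
discovery_config <- function(trim = 0.2, epsilon = NULL, epsilon_q = 0.5,
                             alpha = 0.05, correction = "bonferroni",
                             mode = unrelated_mode("all")) {
  if (trim < 0 || trim > 0.45) stop_("trim must lie in [0, 0.45]")
  correction <- match.arg(correction, "bonferroni")
  if (!is.null(epsilon) && epsilon <= 0) stop_("epsilon must be > 0")
  if (is.null(epsilon) && (epsilon_q <= 0 || epsilon_q >= 1))
    stop_("epsilon_q must lie in (0, 1)")
  structure(list(trim = trim, epsilon = epsilon, epsilon_q = epsilon_q,
                 alpha = alpha, correction = correction, mode = mode),
            class = "discovery_config")
}

# One column per individual: first technical replicate in sheet order.
# Families must have exactly two individuals. Returns index machinery reused
# across probes so each probe is processed in O(pairs) memory.
pair_design <- function(sample_ids, sheet, mode = unrelated_mode("all")) {
  sheet <- sheet[match(sample_ids, sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop_("samples missing from sheet")
  first <- !duplicated(sheet$individual_id)
  idx <- which(first)
  fam <- sheet$family_id[first]
  sizes <- table(fam)
  if (any(sizes != 2))
    stop_("every family must have exactly 2 members; offending: ",
          paste(names(sizes)[sizes != 2], collapse = ", "))
  ord <- order(fam)
  idx <- idx[ord]; fam <- fam[ord]
  n <- length(idx)
  twin_i <- idx[seq(1, n, 2)]
  twin_j <- idx[seq(2, n, 2)]
  same_fam <- outer(fam, fam, `==`)
  ut <- upper.tri(same_fam)
  cross <- which(ut & !same_fam, arr.ind = TRUE)
  un_i <- idx[cross[, 1]]
  un_j <- idx[cross[, 2]]
  if (mode$type == "subsample") {
    if (mode$k > length(un_i)) stop_("k exceeds the number of unrelated pairs")
    keep <- with_seed(mode$seed, sample.int(length(un_i), mode$k))
    un_i <- un_i[keep]; un_j <- un_j[keep]
  } else if (mode$type == "disjoint") {
    m <- with_seed(mode$seed, {
      for (try in 1:10000) {
        perm <- sample.int(n)
        a <- perm[seq(1, n, 2)]; b <- perm[seq(2, n, 2)]
        if (!any(fam[a] == fam[b])) break
        if (try == 10000) stop_("could not draw a co-twin-free matching")
      }
      cbind(a, b)
    })
    un_i <- idx[m[, 1]]; un_j <- idx[m[, 2]]
  }
  list(twin_i = twin_i, twin_j = twin_j, un_i = un_i, un_j = un_j,
       families = fam[seq(1, n, 2)], n_pairs = n / 2)
}

#' Absolute methylation differences for twin and unrelated pairs
#'
#' @param beta_row Named numeric vector of betas, one per sample.
#' @param sheet Sample sheet (`sample_id`, `individual_id`, `family_id`).
#' @param mode An [unrelated_mode()].
#' @return A list with `twin_diffs` (one |dbeta| per MZ family) and
#'   `unrelated_diffs` (over cross-family pairs per the mode).
#' @export
pair_abs_diffs <- function(beta_row, sheet, mode = unrelated_mode("all")) {
  d <- pair_design(names(beta_row), sheet, mode)
  list(twin_diffs = stats::setNames(abs(beta_row[d$twin_i] - beta_row[d$twin_j]),
                                    d$families),
       unrelated_diffs = unname(abs(beta_row[d$un_i] - beta_row[d$un_j])))
}

# Trimmed mean and the Yuen variance term d = (n-1) s2_w / (h (h-1)) from a
# sorted sample.
yuen_terms <- function(xs, trim) {
  n <- length(xs)
  g <- floor(trim * n)
  h <- n - 2 * g
  if (h < 2) stop_("over-trimmed sample: fewer than 2 central observations")
  tm <- mean(xs[(g + 1):(n - g)])
  xw <- pmin(pmax(xs, xs[g + 1]), xs[n - g])
  s2w <- sum((xw - mean(xw))^2) / (n - 1)
  list(tm = tm, d = (n - 1) * s2w / (h * (h - 1)), h = h)
}

#' Yuen-based two one-sided equivalence test
#'
#' Tests whether the gamma-trimmed means of two samples differ by less than
#' the margin `epsilon`, using the Yuen t statistic (trimmed means, winsorized
#' variances, Welch-Satterthwaite degrees of freedom), which tolerates the
#' non-normality of |dbeta| distributions. The two one-sided hypotheses are
#' H0: delta <= -epsilon (p_lower) and H0: delta >= epsilon (p_upper);
#' equivalence holds when both reject, so `p_equiv = max(p_lower, p_upper)`.
#'
#' With `trim = 0` the statistic reduces exactly to the Welch two-sample t.
#' If both winsorized variances vanish, `p_equiv` is 0 when the (exact) mean
#' difference lies inside (-epsilon, epsilon) and 1 otherwise; the result is
#' flagged `degenerate`.
#'
#' @param x,y Numeric samples (length >= 5 each).
#' @param epsilon Equivalence margin (> 0), in the units of `x` and `y`.
#' @param trim Trimming proportion gamma in \[0, 0.5).
#' @return A one-row data frame: `tm_x`, `tm_y`, `delta_hat`, `se`, `df`,
#'   `epsilon`, `p_lower`, `p_upper`, `p_equiv`, `degenerate`.
#' @export
yuen_tost <- function(x, y, epsilon, trim = 0.2) {
  if (length(x) < 5 || length(y) < 5) stop_("both samples need length >= 5")
  if (epsilon <= 0) stop_("epsilon must be > 0")
  if (trim < 0 || trim >= 0.5) stop_("trim must lie in [0, 0.5)")
  a <- yuen_terms(sort(x), trim)
  b <- yuen_terms(sort(y), trim)
  delta <- a$tm - b$tm
  se <- sqrt(a$d + b$d)
  if (se == 0) {
    inside <- abs(delta) < epsilon
    return(data.frame(tm_x = a$tm, tm_y = b$tm, delta_hat = delta, se = 0,
                      df = NA_real_, epsilon = epsilon,
                      p_lower = as.numeric(!inside), p_upper = as.numeric(!inside),
                      p_equiv = as.numeric(!inside), degenerate = TRUE))
  }
  df <- (a$d + b$d)^2 / (a$d^2 / (a$h - 1) + b$d^2 / (b$h - 1))
  p_lower <- 1 - stats::pt((delta + epsilon) / se, df)
  p_upper <- stats::pt((delta - epsilon) / se, df)
  data.frame(tm_x = a$tm, tm_y = b$tm, delta_hat = delta, se = se, df = df,
             epsilon = epsilon, p_lower = p_lower, p_upper = p_upper,
             p_equiv = max(p_lower, p_upper), degenerate = FALSE)
}

#' Calibrate the equivalence margin from twin differences
#'
#' The margin is the `q`-quantile (linear interpolation) of the per-CpG
#' gamma-trimmed means of co-twin |dbeta|, taken across all tested CpGs of a
#' normalization branch. Anchoring epsilon to the co-twin difference scale
#' ties "equivalent" to the resolution actually observed between co-twins.
#'
#' @param tm_twin Vector of per-CpG trimmed means of twin |dbeta|.
#' @param q Quantile in (0, 1).
#' @return The margin epsilon (> 0).
#' @export
calibrate_epsilon <- function(tm_twin, q = 0.5) {
  if (!length(tm_twin)) stop_("empty vector of trimmed twin means")
  if (q <= 0 || q >= 1) stop_("q must lie in (0, 1)")
  eps <- quantile7(tm_twin, q)
  if (eps <= 0) stop_("calibrated epsilon is not positive (all twin differences zero?)")
  eps
}

# Gate one branch; returns the variability table with a `pass` column.
gate_branch <- function(beta, sheet, qc, icc_table = NULL) {
  v <- probe_variability(beta, sheet)
  if (all(is.na(v$icc)) && !is.null(icc_table))
    v$icc <- icc_table$icc[match(v$probe_id, icc_table$probe_id)]
  v$pass <- v$iqr > qc$iqr_min & (is.na(v$icc) | v$icc > qc$icc_min)
  v
}

#' Discover equivalently variable CpGs
#'
#' The full discovery pipeline, per normalization branch: variability gate
#' (IQR, and ICC when available), epsilon calibration from the trimmed twin
#' |dbeta| means, a per-CpG Yuen TOST of twin versus unrelated |dbeta|, and a
#' Bonferroni threshold `alpha / m` with `m` the branch's tested-CpG count.
#' The final evCpG set is the intersection of the per-branch significant sets.
#' Twin/unrelated difference vectors are materialised one probe at a time.
#'
#' @param branches A beta matrix, or a (optionally named) list of beta
#'   matrices sharing probes and samples -- one per normalization method.
#' @param sheet Sample sheet.
#' @param qc A [qc_gate_params()].
#' @param cfg A [discovery_config()].
#' @param icc Optional data frame `(probe_id, icc)` used for gating when the
#'   cohort has no technical replicates.
#' @return An object of class `evcpg_fit`; see [summary.evcpg_fit()].
#' @export
discover_evcpgs <- function(branches, sheet, qc = qc_gate_params(),
                            cfg = discovery_config(), icc = NULL) {
  if (is.matrix(branches)) branches <- list(branches)
  if (!length(branches)) stop_("at least one branch is required")
  if (is.null(names(branches)) || any(!nzchar(names(branches))))
    names(branches) <- paste0("branch", seq_along(branches))
  ref <- rownames(branches[[1]])
  for (b in branches)
    if (!identical(rownames(b), ref) || !identical(colnames(b), colnames(branches[[1]])))
      stop_("branches must share probe and sample ids")
  design <- pair_design(colnames(branches[[1]]), sheet, cfg$mode)

  fit_branch <- function(beta) {
    v <- gate_branch(beta, sheet, qc, icc)
    tested <- v$probe_id[v$pass]
    if (!length(tested))
      return(list(gate = v, results = NULL, epsilon = NA_real_, m = 0L))
    # Pass 1: trimmed twin means only, to calibrate epsilon.
    tm_twin <- vapply(tested, function(p) {
      x <- beta[p, ]
      tw <- sort(abs(x[design$twin_i] - x[design$twin_j]))
      yuen_terms(tw, cfg$trim)$tm
    }, numeric(1))
    eps <- cfg$epsilon %||% calibrate_epsilon(tm_twin, cfg$epsilon_q)
    # Pass 2: full TOST per probe.
    rows <- lapply(tested, function(p) {
      x <- beta[p, ]
      tw <- abs(x[design$twin_i] - x[design$twin_j])
      un <- abs(x[design$un_i] - x[design$un_j])
      yuen_tost(tw, un, eps, cfg$trim)
    })
    res <- do.call(rbind, rows)
    names(res)[names(res) == "tm_x"] <- "tm_twin"
    names(res)[names(res) == "tm_y"] <- "tm_unrel"
    res <- cbind(probe_id = tested, res, stringsAsFactors = FALSE)
    m <- length(tested)
    res$significant <- res$p_equiv < qc$alpha / m
    rownames(res) <- NULL
    list(gate = v, results = res, epsilon = eps, m = m)
  }

  fits <- lapply(branches, fit_branch)
  sig_sets <- lapply(fits, function(f)
    if (is.null(f$results)) character() else f$results$probe_id[f$results$significant])
  evcpgs <- Reduce(intersect, sig_sets)
  structure(list(results = lapply(fits, `[[`, "results"),
                 gate = lapply(fits, `[[`, "gate"),
                 epsilon = vapply(fits, `[[`, numeric(1), "epsilon"),
                 m = vapply(fits, `[[`, integer(1), "m"),
                 alpha = qc$alpha,
                 threshold = qc$alpha / pmax(vapply(fits, `[[`, integer(1), "m"), 1),
                 evcpgs = evcpgs, significant = sig_sets,
                 n_pairs = design$n_pairs,
                 n_unrelated = length(design$un_i),
                 config = cfg, qc = qc),
            class = "evcpg_fit")
}

#' @export
print.evcpg_fit <- function(x, ...) {
  cat("evCpG discovery fit\n")
  cat(sprintf("  branches: %d | twin pairs: %d | unrelated pairs: %d\n",
              length(x$results), x$n_pairs, x$n_unrelated))
  for (b in names(x$results))
    cat(sprintf("  %s: tested %d, epsilon %.4f, significant %d (alpha/m = %.3g)\n",
                b, x$m[[b]], x$epsilon[[b]], length(x$significant[[b]]),
                x$threshold[[b]]))
  cat(sprintf("  evCpGs (intersection): %d\n", length(x$evcpgs)))
  invisible(x)
}

#' Summarise an evCpG discovery fit
#'
#' @param object An `evcpg_fit`.
#' @param ... Unused.
#' @return A list with per-branch counts, margins and the final evCpG set.
#' @export
summary.evcpg_fit <- function(object, ...) {
  out <- list(
    branches = data.frame(
      branch = names(object$results),
      tested = unname(object$m),
      epsilon = unname(object$epsilon),
      threshold = unname(object$threshold),
      significant = vapply(object$significant, length, integer(1)),
      stringsAsFactors = FALSE),
    n_evcpgs = length(object$evcpgs),
    evcpgs = object$evcpgs)
  class(out) <- "summary.evcpg_fit"
  out
}

#' @export
print.summary.evcpg_fit <- function(x, ...) {
  print(x$branches, row.names = FALSE)
  cat(sprintf("evCpGs in the intersection: %d\n", x$n_evcpgs))
  invisible(x)
}

#' Manhattan-style plot of equivalence p-values
#'
#' Plots -log10(p_equiv) per tested CpG for one branch, with the
#' Bonferroni threshold line and the final evCpG set highlighted.
#'
#' @param x An `evcpg_fit`.
#' @param branch Branch name or index (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.evcpg_fit <- function(x, branch = 1, ...) {
  res <- x$results[[branch]]
  if (is.null(res)) stop_("branch has no tested CpGs")
  lp <- -log10(pmax(res$p_equiv, 1e-300))
  thr <- if (is.character(branch)) x$threshold[[branch]] else x$threshold[branch]
  graphics::plot(seq_along(lp), lp, pch = 20,
                 col = ifelse(res$probe_id %in% x$evcpgs, "forestgreen", "grey50"),
                 xlab = "tested CpG index", ylab = "-log10(equivalence p)", ...)
  graphics::abline(h = -log10(thr), lty = 2)
  invisible(x)
}

#' Twin concordance and methylation range per probe
#'
#' Concordance is Lin's concordance correlation coefficient on the
#' order-symmetrised pairing (each twin pair contributes both (a,b) and
#' (b,a), so the result does not depend on which co-twin is listed first);
#' range is `q0.975 - q0.025` of all betas at the probe. Zero-variance probes
#' get concordance 0 with `flag = TRUE`.
#'
#' @param beta Probes x samples matrix.
#' @param sheet Sample sheet.
#' @return Data frame `(probe_id, concordance, range, flag)`.
#' @export
twin_concordance <- function(beta, sheet) {
  d <- pair_design(colnames(beta), sheet)
  t(apply(beta, 1, function(x) {
    a <- x[d$twin_i]; b <- x[d$twin_j]
    xs <- c(a, b); ys <- c(b, a)
    n <- length(xs)
    vx <- sum((xs - mean(xs))^2) / n
    if (vx == 0) c(0, diff(quantile7(x, c(0.025, 0.975))), 1)
    else {
      sxy <- sum((xs - mean(xs)) * (ys - mean(ys))) / n
      c(2 * sxy / (2 * vx), diff(quantile7(x, c(0.025, 0.975))), 0)
    }
  })) -> m
  data.frame(probe_id = rownames(beta), concordance = m[, 1], range = m[, 2],
             flag = as.logical(m[, 3]), stringsAsFactors = FALSE)
}

#' Stability of discovery decisions under independent pairings
#'
#' Re-runs discovery `n_resamples` times with fresh disjoint matchings of
#' unrelated individuals (each individual in at most one pair, never with
#' its co-twin) and reports, per tested CpG, the fraction of runs whose
#' significance decision agrees with the all-pairs run. This guards against
#' the heavy dependence among exhaustive unrelated pairs distorting the
#' equivalence decisions.
#'
#' Decisions are compared at a common *nominal* level (`level`, default the
#' gate's alpha) rather than at each design's Bonferroni threshold: the
#' disjoint design has `n_pairs` unrelated pairs instead of ~`2 n_pairs^2`,
#' so Bonferroni-corrected decisions would mostly measure the power lost to
#' the smaller design, not the dependence distortion the check is after.
#' The baseline Bonferroni decision is still reported per CpG.
#'
#' @param branch Beta matrix (one normalization branch).
#' @param sheet Sample sheet (>= 10 twin pairs).
#' @param qc A [qc_gate_params()].
#' @param cfg A [discovery_config()] (its mode is ignored; all-pairs is the
#'   baseline).
#' @param n_resamples Number of disjoint matchings.
#' @param seed Integer seed; matching r uses `seed + r`.
#' @param level Nominal level at which decisions are compared.
#' @return A list with `per_cpg` (probe id, baseline Bonferroni decision,
#'   baseline nominal decision, agreement fraction), `overall_agreement`
#'   (mean agreement across tested CpGs), and `evcpg_agreement` (restricted
#'   to the baseline Bonferroni-significant set).
#' @export
independence_check <- function(branch, sheet, qc = qc_gate_params(),
                               cfg = discovery_config(), n_resamples = 25,
                               seed = 1, level = qc$alpha) {
  if (pair_design(colnames(branch), sheet)$n_pairs < 10)
    stop_("independence_check needs at least 10 twin pairs")
  base_cfg <- cfg
  base_cfg$mode <- unrelated_mode("all")
  fit0 <- discover_evcpgs(branch, sheet, qc, base_cfg)
  res0 <- fit0$results[[1]]
  dec0 <- res0$p_equiv < level
  agree <- matrix(NA, nrow(res0), n_resamples)
  for (r in seq_len(n_resamples)) {
    cfg_r <- cfg
    cfg_r$mode <- unrelated_mode("disjoint", seed = seed + r)
    fit_r <- discover_evcpgs(branch, sheet, qc, cfg_r)
    res_r <- fit_r$results[[1]]
    stopifnot(identical(res_r$probe_id, res0$probe_id))
    agree[, r] <- (res_r$p_equiv < level) == dec0
  }
  per_cpg <- data.frame(probe_id = res0$probe_id,
                        baseline_significant = res0$significant,
                        baseline_nominal = dec0,
                        agreement = rowMeans(agree), stringsAsFactors = FALSE)
  list(per_cpg = per_cpg,
       overall_agreement = mean(per_cpg$agreement),
       evcpg_agreement = if (any(res0$significant))
         mean(per_cpg$agreement[res0$significant]) else NA_real_)
}
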