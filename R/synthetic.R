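#' Configuration for a synthetic monozygotic-twin array cohort
#'
#' Defines the generative conditions for [simulate_twin_cohort()]. Probes fall
#' into four classes: `error_only` (a single true methylation level shared by
#' everyone, so observed spread is measurement error only), `genetic`
#' (an mQTL-like per-allele shift driven by a family-level genotype shared by
#' co-twins), `stochastic` (an independent per-individual true level, so
#' co-twins differ as much as unrelated individuals -- the evCpG model), and
#' `mixed` (genotype effect plus per-individual noise).
#'
#' Measurement noise is additive Normal on the log-odds (logit) scale followed
#' by the inverse-logit, which keeps observed values strictly inside (0,1) and
#' makes variance components analytic on the logit scale.
#'
#' @param n_pairs Number of MZ twin families (>= 2).
#' @param n_cpgs Number of probes (>= 1).
#' @param class_fractions Named fractions over
#'   `c("error_only","genetic","stochastic","mixed")`; must sum to 1.
#' @param sigma_meas Measurement-error SD on the logit scale.
#' @param sigma_stoch Stochastic inter-individual SD on the logit scale.
#' @param maf_range Interval in (0, 0.5] for simulated allele frequencies.
#' @param effect_range Per-allele beta-shift interval in \[0, 0.3\].
#' @param batch_shift Logit-scale offset between successive batches.
#' @param n_batches Number of batches samples are assigned to (round-robin).
#' @param baseline_range Baseline true-beta interval for error_only/genetic
#'   probes.
#' @param baseline_range_stoch Baseline interval for stochastic/mixed probes
#'   (kept mid-range so their spread clears the variability gate).
#' @param seed Integer seed; fixing it fixes every output bit-exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 200, n_cpgs = 5000,
                          class_fractions = c(error_only = 0.70, genetic = 0.20,
                                              stochastic = 0.05, mixed = 0.05),
                          sigma_meas = 0.12, sigma_stoch = 0.25,
                          maf_range = c(0.1, 0.5), effect_range = c(0.1, 0.3),
                          batch_shift = 0, n_batches = 1,
                          baseline_range = c(0.1, 0.9),
                          baseline_range_stoch = c(0.3, 0.7),
                          seed = 1) {
  classes <- c("error_only", "genetic", "stochastic", "mixed")
  if (!setequal(names(class_fractions), classes))
    stop_("class_fractions must be named over: ", paste(classes, collapse = ", "))
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop_("class_fractions must be non-negative and sum to 1")
  if (!is_count(n_pairs) || n_pairs < 2) stop_("n_pairs must be an integer >= 2")
  if (!is_count(n_cpgs) || n_cpgs < 1) stop_("n_cpgs must be an integer >= 1")
  if (sigma_meas < 0 || sigma_stoch < 0 || batch_shift < 0)
    stop_("scales must be >= 0")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || diff(maf_range) < 0)
    stop_("maf_range must be an interval within (0, 0.5]")
  if (effect_range[1] < 0 || effect_range[2] > 0.3 || diff(effect_range) < 0)
    stop_("effect_range must be an interval within [0, 0.3]")
  if (!is_count(n_batches) || n_batches < 1) stop_("n_batches must be >= 1")
  structure(list(n_pairs = n_pairs, n_cpgs = n_cpgs,
                 class_fractions = class_fractions, sigma_meas = sigma_meas,
                 sigma_stoch = sigma_stoch, maf_range = maf_range,
                 effect_range = effect_range, batch_shift = batch_shift,
                 n_batches = n_batches, baseline_range = baseline_range,
                 baseline_range_stoch = baseline_range_stoch,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic class counts: floor shares, remainder to the largest
# fractional parts (ties broken by class order).
class_counts <- function(fracs, n) {
  base <- floor(fracs * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_part <- fracs * n - base
    ord <- order(-frac_part, seq_along(fracs))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Simulate an array-style MZ twin cohort
#'
#' Generates a probes x samples beta-value matrix for `2 * n_pairs`
#' individuals, a sample sheet, and a ground-truth table recording each
#' probe's class and generative parameters. Observed values are
#' `inverse-logit(logit(true) + N(0, sigma_meas) + batch offset)`; true
#' betas are clamped to \[0.001, 0.999\] before the logit.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `beta` (matrix; carries the true-beta matrix
#'   and the config as attributes so replicates can be re-observed), `sheet`
#'   (data.frame) and `truth` (data.frame).
#' @export
simulate_twin_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_("config must be a cohort_config")
  n_ind <- 2L * config$n_pairs
  counts <- class_counts(config$class_fractions, config$n_cpgs)
  cls <- rep(names(counts), counts)
  probe_id <- sprintf("cg%06d", seq_len(config$n_cpgs))
  fam <- sprintf("F%04d", rep(seq_len(config$n_pairs), each = 2))
  sample_id <- paste0(fam, "_T", rep(1:2, config$n_pairs))
  batch <- ((seq_len(n_ind) - 1L) %% config$n_batches) + 1L
  fam_idx <- rep(seq_len(config$n_pairs), each = 2)

  with_seed(config$seed, {
    sex <- rep(sample(c("F", "M"), config$n_pairs, replace = TRUE), each = 2)
    baseline <- numeric(config$n_cpgs)
    mid <- cls %in% c("stochastic", "mixed")
    baseline[!mid] <- runif(sum(!mid), config$baseline_range[1], config$baseline_range[2])
    baseline[mid] <- runif(sum(mid), config$baseline_range_stoch[1],
                           config$baseline_range_stoch[2])
    maf <- effect <- rep(NA_real_, config$n_cpgs)
    gen <- cls %in% c("genetic", "mixed")
    maf[gen] <- runif(sum(gen), config$maf_range[1], config$maf_range[2])
    effect[gen] <- runif(sum(gen), config$effect_range[1], config$effect_range[2])

    true_beta <- matrix(rep(baseline, n_ind), nrow = config$n_cpgs)
    if (any(gen)) {
      # Hardy-Weinberg genotypes at the family level: co-twins share them.
      g_fam <- matrix(rbinom(sum(gen) * config$n_pairs, 2, rep(maf[gen], config$n_pairs)),
                      nrow = sum(gen))
      true_beta[gen, ] <- clamp_beta(baseline[gen] + effect[gen] * g_fam[, fam_idx],
                                     0.001, 0.999)
      genotypes <- g_fam
    } else genotypes <- NULL
    sto <- cls %in% c("stochastic", "mixed")
    if (any(sto) && config$sigma_stoch > 0) {
      noise <- matrix(rnorm(sum(sto) * n_ind, 0, config$sigma_stoch), nrow = sum(sto))
      true_beta[sto, ] <- inv_logit(logit(clamp_beta(true_beta[sto, , drop = FALSE])) + noise)
    }
    true_beta <- clamp_beta(true_beta)
    offs <- config$batch_shift * (batch - 1L)
    meas <- if (config$sigma_meas > 0)
      matrix(rnorm(length(true_beta), 0, config$sigma_meas), nrow = nrow(true_beta))
    else 0
    beta <- inv_logit(sweep(logit(true_beta) + meas, 2, offs, `+`))
    dimnames(beta) <- dimnames(true_beta) <- list(probe_id, sample_id)

    sheet <- data.frame(sample_id = sample_id, individual_id = sample_id,
                        family_id = fam, role = rep(c("twin1", "twin2"), config$n_pairs),
                        age = 18, sex = sex, batch = batch, replicate_id = 1L,
                        tissue = "blood", stringsAsFactors = FALSE)
    truth <- data.frame(probe_id = probe_id, class = cls, baseline = baseline,
                        effect = effect, maf = maf, stringsAsFactors = FALSE)
    attr(beta, "true_beta") <- true_beta
    attr(beta, "config") <- config
    if (!is.null(genotypes)) attr(beta, "genotypes") <- genotypes
    list(beta = beta, sheet = sheet, truth = truth)
  })
}

#' Simulate technical or longitudinal replicates of a synthetic cohort
#'
#' Technical replicates re-observe the same true methylation values with fresh
#' measurement noise and a per-chip batch offset (replicate round r is one
#' chip). Longitudinal replicates let the true logit perform a random walk
#' with per-step SD `sigma_time`, then observe with fresh noise.
#'
#' @param base Beta matrix produced by [simulate_twin_cohort()].
#' @param sheet Its sample sheet.
#' @param truth Its truth table (carried through unchanged).
#' @param mode `"technical"` or `"longitudinal"`.
#' @param k Number of replicates/timepoints (>= 2).
#' @param sigma_time Logit-scale random-walk step SD (longitudinal only).
#' @param seed Integer seed.
#' @param n_batches,batch_shift Chip structure for technical replicates;
#'   default taken from the base config.
#' @return A list with the replicated `beta` matrix and the expanded `sheet`.
#' @export
simulate_replicates <- function(base, sheet, truth,
                                mode = c("technical", "longitudinal"),
                                k = 2, sigma_time = 0.05, seed = 1,
                                n_batches = NULL, batch_shift = NULL) {
  mode <- match.arg(mode)
  true_beta <- attr(base, "true_beta")
  config <- attr(base, "config")
  if (is.null(true_beta) || is.null(config))
    stop_("'base' must carry true values: generate it with simulate_twin_cohort()")
  if (!is_count(k) || k < 2) stop_("k must be an integer >= 2")
  n_batches <- n_batches %||% config$n_batches
  batch_shift <- batch_shift %||% config$batch_shift
  n_ind <- ncol(base)
  n_cpg <- nrow(base)

  with_seed(seed, {
    cols <- vector("list", k)
    lt <- logit(true_beta)
    for (r in seq_len(k)) {
      if (mode == "longitudinal" && r > 1 && sigma_time > 0)
        lt <- lt + matrix(rnorm(n_cpg * n_ind, 0, sigma_time), nrow = n_cpg)
      off <- if (mode == "technical") batch_shift * (((r - 1L) %% n_batches)) else 0
      meas <- if (config$sigma_meas > 0)
        matrix(rnorm(n_cpg * n_ind, 0, config$sigma_meas), nrow = n_cpg) else 0
      cols[[r]] <- inv_logit(lt + meas + off)
    }
    suffix <- if (mode == "technical") "_R" else "_T"
    out <- matrix(NA_real_, n_cpg, n_ind * k)
    ids <- character(n_ind * k)
    sheets <- vector("list", n_ind * k)
    j <- 0L
    for (i in seq_len(n_ind)) for (r in seq_len(k)) {
      j <- j + 1L
      out[, j] <- cols[[r]][, i]
      ids[j] <- paste0(colnames(base)[i], suffix, r)
      row <- sheet[i, , drop = FALSE]
      row$sample_id <- ids[j]
      if (mode == "technical") {
        row$replicate_id <- r
        row$batch <- ((r - 1L) %% n_batches) + 1L
      } else row$timepoint <- r
      sheets[[j]] <- row
    }
    dimnames(out) <- list(rownames(base), ids)
    new_sheet <- do.call(rbind, sheets)
    rownames(new_sheet) <- NULL
    list(beta = out, sheet = new_sheet)
  })
}

#' Simulate a cross-sectional aging cohort
#'
#' Ages are Uniform over `age_range`. Clock CpGs shift their mean logit
#' linearly with age; drift CpGs grow their logit SD linearly with age above
#' the measurement-error floor (`sd = sigma_meas + drift_rate * (age - min)`);
#' `neither` CpGs are constant. Sex is Bernoulli(0.5) and does not enter the
#' generative model.
#'
#' @param n Number of individuals (>= 30).
#' @param age_range Interval of ages in years (positive width).
#' @param n_cpgs Named counts `c(clock=, drift=, neither=)`.
#' @param clock_slope Logit shift per year for clock CpGs.
#' @param drift_rate Logit-SD growth per year for drift CpGs.
#' @param sigma_meas Measurement-error SD on the logit scale.
#' @param baseline_range Baseline true-beta interval.
#' @param seed Integer seed.
#' @return A list with `beta`, `sheet` (sample_id, age, sex) and `truth`.
#' @export
simulate_aging_cohort <- function(n, age_range = c(14, 94),
                                  n_cpgs = c(clock = 50, drift = 50, neither = 200),
                                  clock_slope = 0.01, drift_rate = 0.005,
                                  sigma_meas = 0.12, baseline_range = c(0.3, 0.7),
                                  seed = 1) {
  if (!is_count(n) || n < 30) stop_("n must be an integer >= 30")
  if (diff(age_range) <= 0) stop_("age_range must have positive width")
  if (!all(c("clock", "drift", "neither") %in% names(n_cpgs)))
    stop_("n_cpgs must be named over clock, drift, neither")
  n_cpgs <- n_cpgs[c("clock", "drift", "neither")]
  m <- sum(n_cpgs)
  cls <- rep(names(n_cpgs), n_cpgs)
  probe_id <- sprintf("ag%06d", seq_len(m))
  sample_id <- sprintf("S%04d", seq_len(n))
  with_seed(seed, {
    age <- runif(n, age_range[1], age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    baseline <- runif(m, baseline_range[1], baseline_range[2])
    mu <- matrix(rep(logit(clamp_beta(baseline)), n), nrow = m)
    ck <- cls == "clock"
    if (any(ck))
      mu[ck, ] <- mu[ck, , drop = FALSE] +
        outer(rep(clock_slope, sum(ck)), age - mean(age_range))
    sd_mat <- matrix(sigma_meas, m, n)
    dr <- cls == "drift"
    if (any(dr))
      sd_mat[dr, ] <- sigma_meas +
        outer(rep(drift_rate, sum(dr)), age - age_range[1])
    beta <- inv_logit(mu + matrix(rnorm(m * n), m, n) * sd_mat)
    dimnames(beta) <- list(probe_id, sample_id)
    sheet <- data.frame(sample_id = sample_id, individual_id = sample_id,
                        age = age, sex = sex, stringsAsFactors = FALSE)
    effect <- rep(0, m)
    effect[ck] <- clock_slope
    effect[dr] <- drift_rate
    truth <- data.frame(probe_id = probe_id, class = cls, baseline = baseline,
                        effect = effect, stringsAsFactors = FALSE)
    list(beta = beta, sheet = sheet, truth = truth)
  })
}

#' Configuration for a synthetic WGBS twin pair
#'
#' @param n_sites Number of CpG sites on the toy chromosome.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param mean_coverage Mean per-site read coverage (> 0).
#' @param coverage_dispersion Negative-binomial size parameter; the
#'   overdispersion mimics real WGBS coverage.
#' @param region `(start, end)` bp (1-based inclusive) of the
#'   discordance-enriched locus; must lie within the chromosome.
#' @param frac_discordant_in_region Fraction of in-region sites given
#'   twin-specific true betas with absolute difference >= 0.5.
#' @param frac_blacklist Fraction of sites flagged and emitted in the
#'   blacklist interval set.
#' @param frac_strand_artifact Per-twin fraction of sites whose minus-strand
#'   methylation level is corrupted to force a > 20 percentage-point strand
#'   difference.
#' @param beta_shape Beta-distribution shape pair for true methylation levels
#'   (bimodal by default, as for real CpGs).
#' @param seed Integer seed.
#' @return An object of class `wgbs_sim_config`.
#' @export
wgbs_sim_config <- function(n_sites = 20000, chrom = "chrS", chrom_length = 1e7,
                            mean_coverage = 30, coverage_dispersion = 5,
                            region = c(4e6, 4.5e6),
                            frac_discordant_in_region = 0.3,
                            frac_blacklist = 0.02, frac_strand_artifact = 0.01,
                            beta_shape = c(0.3, 0.3), seed = 1) {
  if (mean_coverage <= 0) stop_("mean_coverage must be > 0")
  if (coverage_dispersion <= 0) stop_("coverage_dispersion must be > 0")
  fr <- c(frac_discordant_in_region, frac_blacklist, frac_strand_artifact)
  if (any(fr < 0 | fr > 1)) stop_("fractions must lie in [0, 1]")
  if (region[1] < 1 || region[2] > chrom_length || region[1] >= region[2])
    stop_("region must lie within [1, chrom_length)")
  if (!is_count(n_sites) || n_sites < 1) stop_("n_sites must be a positive integer")
  structure(list(n_sites = n_sites, chrom = chrom, chrom_length = chrom_length,
                 mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion, region = region,
                 frac_discordant_in_region = frac_discordant_in_region,
                 frac_blacklist = frac_blacklist,
                 frac_strand_artifact = frac_strand_artifact,
                 beta_shape = beta_shape, seed = as.integer(seed)),
            class = "wgbs_sim_config")
}

# Draw per-strand count rows for one twin.
wgbs_twin_table <- function(chrom, pos, tb, tb_minus, cov) {
  keep <- cov > 0
  pos <- pos[keep]; tb <- tb[keep]; tb_minus <- tb_minus[keep]; cov <- cov[keep]
  plus <- rbinom(length(cov), cov, 0.5)
  minus <- cov - plus
  meth_p <- rbinom(length(cov), plus, tb)
  meth_m <- rbinom(length(cov), minus, tb_minus)
  df <- rbind(
    data.frame(chrom = chrom, pos = pos, strand = "+",
               count_methylated = meth_p, count_total = plus,
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, pos = pos, strand = "-",
               count_methylated = meth_m, count_total = minus,
               stringsAsFactors = FALSE))
  df <- df[df$count_total > 0, ]
  df <- df[order(df$pos, df$strand), ]
  df$beta <- df$count_methylated / df$count_total
  rownames(df) <- NULL
  df
}

#' Simulate a WGBS MZ twin pair with a discordance-enriched region
#'
#' Sites are placed uniformly on a toy chromosome; per-site coverage is
#' negative binomial per twin; methylated reads are Binomial(coverage, true
#' beta) split binomially across strands. Outside the configured region
#' co-twins share the true beta; inside it a configured fraction of sites get
#' twin-specific levels with absolute true difference >= 0.5. A fraction of
#' sites is emitted in a blacklist interval set, and a per-twin fraction gets
#' a corrupted minus strand (forced > 20 percentage-point strand difference).
#'
#' @param config A [wgbs_sim_config()].
#' @return A list with `twin1`/`twin2` per-strand site tables (chrom, pos,
#'   strand, count_methylated, count_total, beta), `blacklist` (a `region_set`,
#'   1-based inclusive intervals), and `truth` (per-site labels and true
#'   betas).
#' @export
simulate_wgbs_pair <- function(config) {
  if (!inherits(config, "wgbs_sim_config")) stop_("config must be a wgbs_sim_config")
  with_seed(config$seed, {
    pos <- sort(sample.int(config$chrom_length, config$n_sites))
    b <- clamp_beta(rbeta(config$n_sites, config$beta_shape[1], config$beta_shape[2]),
                    0.001, 0.999)
    in_region <- pos >= config$region[1] & pos <= config$region[2]
    disc <- in_region & runif(config$n_sites) < config$frac_discordant_in_region
    b1 <- b2 <- b
    nd <- sum(disc)
    if (nd > 0) {
      lo <- runif(nd, 0.02, 0.3)
      hi <- lo + runif(nd, 0.5, pmin(0.7, 0.98 - lo))
      swap <- runif(nd) < 0.5
      b1[disc] <- ifelse(swap, hi, lo)
      b2[disc] <- ifelse(swap, lo, hi)
    }
    black <- runif(config$n_sites) < config$frac_blacklist
    art1 <- runif(config$n_sites) < config$frac_strand_artifact
    art2 <- runif(config$n_sites) < config$frac_strand_artifact
    corrupt <- function(bb) clamp_beta(bb + ifelse(bb < 0.5, 0.6, -0.6), 0.001, 0.999)
    bm1 <- ifelse(art1, corrupt(b1), b1)
    bm2 <- ifelse(art2, corrupt(b2), b2)
    cov1 <- rnbinom(config$n_sites, size = config$coverage_dispersion,
                    mu = config$mean_coverage)
    cov2 <- rnbinom(config$n_sites, size = config$coverage_dispersion,
                    mu = config$mean_coverage)
    twin1 <- wgbs_twin_table(config$chrom, pos, b1, bm1, cov1)
    twin2 <- wgbs_twin_table(config$chrom, pos, b2, bm2, cov2)
    blk <- if (any(black))
      merge_regions(data.frame(chrom = config$chrom, start = pos[black],
                               end = pos[black], stringsAsFactors = FALSE))
    else data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
    class(blk) <- c("region_set", "data.frame")
    truth <- data.frame(chrom = config$chrom, pos = pos, in_region = in_region,
                        discordant = disc, blacklisted = black,
                        artifact_t1 = art1, artifact_t2 = art2,
                        true_beta1 = b1, true_beta2 = b2,
                        stringsAsFactors = FALSE)
    list(twin1 = twin1, twin2 = twin2, blacklist = blk, truth = truth)
  })
}
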