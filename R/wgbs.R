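#' WGBS site-filter thresholds
#'
#' Defaults follow the conservative pre-processing used for twin WGBS
#' comparisons: sites with more than a 20 percentage-point methylation
#' difference between strands are excluded, as are sites with coverage
#' less than or equal to 10 reads or above the per-sample 99.9% coverage
#' quantile (PCR artefacts); twin discordance calls use |dbeta| >= 0.4, the
#' 95% sampling quantile at 10 reads (see [sampling_quantile_threshold()]).
#'
#' @param max_strand_diff Maximum tolerated |beta_plus - beta_minus|.
#' @param min_coverage Sites with `count_total <= min_coverage` are removed.
#' @param high_quantile Per-sample coverage quantile above which sites are
#'   removed.
#' @param delta_threshold Twin |dbeta| discordance call threshold.
#' @param quantile_level Level used when deriving `delta_threshold` from
#'   coverage.
#' @return An object of class `wgbs_filters`.
#' @export
wgbs_filters <- function(max_strand_diff = 0.20, min_coverage = 10,
                         high_quantile = 0.999, delta_threshold = 0.40,
                         quantile_level = 0.95) {
  if (min_coverage < 1) stop_("min_coverage must be >= 1")
  chk <- c(max_strand_diff, high_quantile, delta_threshold, quantile_level)
  if (any(chk < 0 | chk > 1)) stop_("thresholds must lie in [0, 1]")
  structure(list(max_strand_diff = max_strand_diff, min_coverage = min_coverage,
                 high_quantile = high_quantile, delta_threshold = delta_threshold,
                 quantile_level = quantile_level),
            class = "wgbs_filters")
}

# TRUE for positions covered by any interval of a 1-based inclusive region set.
positions_in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (is.null(regions) || !nrow(regions)) return(hit)
  for (cr in unique(regions$chrom)) {
    r <- regions[regions$chrom == cr, ]
    sel <- chrom == cr
    if (!any(sel)) next
    # intervals are sorted and merged; findInterval locates the candidate.
    i <- findInterval(pos[sel], r$start)
    ok <- i >= 1 & pos[sel] <= r$end[pmax(i, 1)]
    hit[sel] <- ok & i >= 1
  }
  hit
}

# Per-sample filter chain: strand check + merge, blacklist, coverage.
filter_one_sample <- function(tab, blacklists, filters) {
  audit <- c(strand_discordant = 0L, blacklisted = 0L,
             low_coverage = 0L, high_coverage = 0L)
  key <- paste(tab$chrom, tab$pos)
  # (1) strand concordance: only sites covered on both strands are checked;
  # concordant sites have their counts summed across strands.
  first <- !duplicated(key)
  n_sites_in <- sum(first)
  meth <- rowsum(tab$count_methylated, key, reorder = FALSE)[, 1]
  tot <- rowsum(tab$count_total, key, reorder = FALSE)[, 1]
  nstr <- rowsum(rep(1L, nrow(tab)), key, reorder = FALSE)[, 1]
  beta_by_strand <- split(tab$beta, factor(key, levels = unique(key)))
  both <- nstr == 2
  sdiff <- rep(0, length(tot))
  sdiff[both] <- vapply(beta_by_strand[both], function(b) abs(b[1] - b[2]),
                        numeric(1))
  drop1 <- sdiff > filters$max_strand_diff
  audit["strand_discordant"] <- sum(drop1)
  merged <- data.frame(chrom = tab$chrom[first], pos = tab$pos[first],
                       count_methylated = unname(meth), count_total = unname(tot),
                       stringsAsFactors = FALSE)[!drop1, ]
  # (2) blacklist intervals
  bl <- rep(FALSE, nrow(merged))
  for (regions in blacklists)
    bl <- bl | positions_in_regions(merged$chrom, merged$pos, regions)
  audit["blacklisted"] <- sum(bl)
  merged <- merged[!bl, ]
  # (3) low coverage (inclusive cut: total <= min_coverage removed)
  low <- merged$count_total <= filters$min_coverage
  audit["low_coverage"] <- sum(low)
  merged <- merged[!low, ]
  # (4) high coverage: per-sample quantile computed after steps 1-3
  if (nrow(merged)) {
    hq <- quantile7(merged$count_total, filters$high_quantile)
    high <- merged$count_total > hq
    audit["high_coverage"] <- sum(high)
    merged <- merged[!high, ]
  } else hq <- NA_real_
  merged$beta <- merged$count_methylated / merged$count_total
  rownames(merged) <- NULL
  list(sites = merged, audit = audit, n_in = n_sites_in,
       high_cut = unname(hq))
}

#' Pre-process a WGBS twin pair into a shared-site |dbeta| table
#'
#' Per sample, in order: (1) drop CpGs covered on both strands whose
#' strand-level betas differ by more than `max_strand_diff`, summing counts
#' across strands otherwise (single-strand sites pass vacuously); (2) drop
#' sites inside any blacklist interval; (3) drop sites with
#' `count_total <= min_coverage`; (4) drop sites above the per-sample
#' `high_quantile` coverage quantile (computed after steps 1-3). Then keep
#' only `(chrom, pos)` present in both twins and emit per-site |dbeta| with a
#' per-step removal audit.
#'
#' @param twin1,twin2 Per-strand site tables
#'   `(chrom, pos, strand, count_methylated, count_total, beta)`, sorted by
#'   `(chrom, pos)`; see [read_wgbs_sites()] or [simulate_wgbs_pair()].
#' @param blacklists A `region_set` or list of them (1-based inclusive).
#' @param filters A [wgbs_filters()].
#' @return A list with `sites` (shared-site table with `beta1`, `beta2`,
#'   `dbeta`) and `audit` (per-twin removal counts, shared-site counts and
#'   high-coverage cuts). An empty shared set is returned with a warning.
#' @export
preprocess_wgbs <- function(twin1, twin2, blacklists = list(),
                            filters = wgbs_filters()) {
  for (tab in list(twin1, twin2)) {
    if (!all(c("chrom", "pos", "count_methylated", "count_total") %in% names(tab)))
      stop_("site tables need chrom, pos, count_methylated, count_total")
    if (any(order(tab$chrom, tab$pos) != seq_len(nrow(tab))))
      stop_("site tables must be sorted by (chrom, pos)")
  }
  if (inherits(blacklists, "region_set")) blacklists <- list(blacklists)
  f1 <- filter_one_sample(twin1, blacklists, filters)
  f2 <- filter_one_sample(twin2, blacklists, filters)
  k1 <- paste(f1$sites$chrom, f1$sites$pos)
  k2 <- paste(f2$sites$chrom, f2$sites$pos)
  shared <- intersect(k1, k2)
  i1 <- match(shared, k1); i2 <- match(shared, k2)
  sites <- data.frame(chrom = f1$sites$chrom[i1], pos = f1$sites$pos[i1],
                      total1 = f1$sites$count_total[i1],
                      total2 = f2$sites$count_total[i2],
                      beta1 = f1$sites$beta[i1], beta2 = f2$sites$beta[i2],
                      stringsAsFactors = FALSE)
  sites$dbeta <- abs(sites$beta1 - sites$beta2)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  if (!nrow(sites)) warning("no sites shared between twins")
  audit <- data.frame(twin = c("twin1", "twin2"),
                      sites_in = c(f1$n_in, f2$n_in),
                      rbind(f1$audit, f2$audit),
                      unshared = c(length(k1), length(k2)) - length(shared),
                      shared = length(shared),
                      high_cut = c(f1$high_cut, f2$high_cut))
  rownames(audit) <- NULL
  list(sites = sites, audit = audit)
}

#' Sampling-noise |dbeta| threshold at a given coverage
#'
#' Exact enumeration of the absolute difference of two independent
#' Binomial(coverage, p) methylation proportions with *no* true difference:
#' returns the smallest grid value `q = d / coverage` whose cumulative
#' probability reaches `level`. Differences at or above the threshold are
#' unlikely to arise from read sampling alone; at 10 reads, p = 0.5 and the
#' 95% level the threshold is 0.4. The default p = 0.5 maximises binomial
#' variance and hence gives the most conservative threshold.
#'
#' @param coverage Reads per site (>= 1).
#' @param p True methylation level in (0, 1).
#' @param level Quantile level in (0, 1).
#' @return The |dbeta| threshold on the `d / coverage` grid.
#' @export
sampling_quantile_threshold <- function(coverage, p = 0.5, level = 0.95) {
  if (!is_count(coverage) || coverage < 1) stop_("coverage must be an integer >= 1")
  if (p <= 0 || p >= 1) stop_("p must lie in (0, 1)")
  if (level <= 0 || level >= 1) stop_("level must lie in (0, 1)")
  f <- stats::dbinom(0:coverage, coverage, p)
  joint <- outer(f, f)                      # P(X1 = i, X2 = j)
  d <- abs(outer(0:coverage, 0:coverage, `-`))
  pmf <- rowsum(as.vector(joint), as.vector(d))[, 1]   # grouped by d = 0..coverage
  cdf <- cumsum(pmf)
  unname((which(cdf >= level)[1] - 1) / coverage)
}

#' Regional enrichment of twin-discordant sites
#'
#' Builds the 2x2 table of shared sites with |dbeta| at/above versus below
#' the discordance threshold, inside versus outside the region, and tests
#' enrichment with a one-sided (greater) Fisher exact test. The odds ratio
#' is `ad / bc`, with a 0.5 Haldane-Anscombe correction (flagged) when any
#' cell is zero.
#'
#' @param sites Shared-site table from [preprocess_wgbs()].
#' @param region List or vector `(chrom, start, end)`, 1-based inclusive
#'   (e.g. the clustered-protocadherin locus chr5:140165876-140892546, hg19).
#' @param delta_threshold Discordance call threshold (default 0.4).
#' @return A one-row data frame `(a, b, c, d, odds_ratio, p, or_corrected,
#'   status)`; `status = "no_covered_sites_in_region"` when the region has no
#'   shared sites, in which case the test is not computed.
#' @export
region_discordance_enrichment <- function(sites, region, delta_threshold = 0.4) {
  if (!nrow(sites)) stop_("empty shared-site table")
  if (is.list(region) && !is.data.frame(region))
    region <- c(region$chrom, region$start, region$end)
  chrom <- as.character(region[1])
  start <- as.numeric(region[2]); end <- as.numeric(region[3])
  inr <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
  disc <- sites$dbeta >= delta_threshold
  a <- sum(inr & disc); b <- sum(inr & !disc)
  c_ <- sum(!inr & disc); d <- sum(!inr & !disc)
  if (a + b == 0)
    return(data.frame(a = a, b = b, c = c_, d = d, odds_ratio = NA_real_,
                      p = NA_real_, or_corrected = FALSE,
                      status = "no_covered_sites_in_region",
                      stringsAsFactors = FALSE))
  or <- odds_ratio_adbc(a, b, c_, d)
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or[1],
             p = fisher_p(a, b, c_, d, "greater"),
             or_corrected = as.logical(or[2]), status = "ok",
             stringsAsFactors = FALSE)
}
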