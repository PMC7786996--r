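#' Annotation-category enrichment of a probe set
#'
#' Per category, builds the 2x2 table (targets in/out of the category versus
#' background in/out) and runs a Fisher exact test with the chosen
#' sidedness, Bonferroni-corrected across categories. The background is
#' expected to exclude the target set (the usual contrast is against the
#' variably methylated probes that were *not* selected); pass
#' `background_excludes_target = FALSE` for an inclusive background, in
#' which case targets are removed from it first.
#'
#' @param target Character vector of probe ids.
#' @param background Character vector of probe ids.
#' @param annotation Data frame `(probe_id, label)` for one annotation
#'   scheme; probes may carry several labels (several rows).
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @param background_excludes_target Set `FALSE` when `background` still
#'   contains the targets.
#' @return An `EnrichmentTable` data frame: one row per category with
#'   `a, b, c, d`, `odds_ratio` (ad/bc, Haldane-Anscombe corrected and
#'   flagged when a cell is zero), `p`, `p_adj` (Bonferroni) and
#'   `direction`.
#' @export
category_enrichment <- function(target, background, annotation,
                                sided = c("two", "greater", "less"),
                                background_excludes_target = TRUE) {
  sided <- match.arg(sided)
  if (!length(target) || !length(background))
    stop_("target and background must be non-empty")
  if (!background_excludes_target)
    background <- setdiff(background, target)
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[sided]]
  cats <- sort(unique(annotation$label))
  rows <- lapply(cats, function(cat) {
    inset <- unique(annotation$probe_id[annotation$label == cat])
    a <- sum(target %in% inset); b <- length(target) - a
    c_ <- sum(background %in% inset); d <- length(background) - c_
    or <- odds_ratio_adbc(a, b, c_, d)
    data.frame(unit = cat, a = a, b = b, c = c_, d = d, odds_ratio = or[1],
               p = fisher_p(a, b, c_, d, alt),
               or_corrected = as.logical(or[2]),
               direction = if (or[1] >= 1) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out
}

# Merge overlapping [start, end] windows per chromosome; positions sorted.
merge_windows <- function(df) {
  out <- lapply(split(df, df$chrom), function(g) {
    g <- g[order(g$start), ]
    s <- g$start[1]; e <- g$end[1]
    res <- list()
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= e) e <- max(e, g$end[i])
      else { res[[length(res) + 1]] <- c(s, e); s <- g$start[i]; e <- g$end[i] }
    }
    res[[length(res) + 1]] <- c(s, e)
    data.frame(chrom = g$chrom[1], start = sapply(res, `[`, 1),
               end = sapply(res, `[`, 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unbiased positional enrichment in merged windows around target sites
#'
#' Centres a window of +/- `window / 2` bp on every target position, merges
#' overlapping windows per chromosome, and tests each merged window for
#' enrichment of targets versus background positions (inside vs outside,
#' one-sided greater Fisher test, Bonferroni across merged windows). Rows
#' are ordered with multi-target windows first, then by p-value, so
#' clustered loci surface at the top.
#'
#' @param target Data frame `(chrom, pos)` of target sites.
#' @param background Data frame `(chrom, pos)` of background sites.
#' @param window Window width in bp (default 1000).
#' @return An `EnrichmentTable` data frame keyed by window coordinates, with
#'   `n_targets` per merged window.
#' @export
positional_enrichment <- function(target, background, window = 1000) {
  if (!nrow(target)) stop_("no target positions")
  half <- window / 2
  win <- merge_windows(data.frame(chrom = target$chrom,
                                  start = pmax(1, target$pos - half),
                                  end = target$pos + half,
                                  stringsAsFactors = FALSE))
  nt <- length(target$pos); nb <- length(background$pos)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    w <- win[i, ]
    a <- sum(target$chrom == w$chrom & target$pos >= w$start & target$pos <= w$end)
    c_ <- sum(background$chrom == w$chrom & background$pos >= w$start &
                background$pos <= w$end)
    b <- nt - a; d <- nb - c_
    or <- odds_ratio_adbc(a, b, c_, d)
    data.frame(unit = sprintf("%s:%d-%d", w$chrom, round(w$start), round(w$end)),
               chrom = w$chrom, start = w$start, end = w$end, n_targets = a,
               a = a, b = b, c = c_, d = d, odds_ratio = or[1],
               p = fisher_p(a, b, c_, d, "greater"),
               or_corrected = as.logical(or[2]),
               direction = if (or[1] >= 1) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out[order(out$n_targets < 2, out$p), ]
}

gc_fraction <- function(seqs) {
  vapply(toupper(seqs), function(s) {
    b <- strsplit(s, "")[[1]]
    b <- b[b != "N"]
    if (!length(b)) return(NA_real_)
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compare \[G+C\] content between two sequence sets
#'
#' Computes the per-sequence \[G+C\] fraction (Ns excluded from the
#' denominator) and compares the sets with a two-sided Mann-Whitney U test
#' (normal approximation with tie and continuity correction).
#'
#' @param target,background Character vectors of A/C/G/T/N sequences.
#' @return A list with `gc_target`, `gc_background`, `statistic` (U for the
#'   target set), `p`, and `direction` (`"diminished"`/`"elevated"` for the
#'   target relative to background).
#' @export
gc_content_comparison <- function(target, background) {
  if (!length(target) || !length(background)) stop_("empty sequence set")
  gt <- gc_fraction(target); gb <- gc_fraction(background)
  wt <- stats::wilcox.test(gt, gb, exact = FALSE, correct = TRUE)
  list(gc_target = gt, gc_background = gb,
       statistic = unname(wt$statistic), p = wt$p.value,
       direction = if (stats::median(gt) < stats::median(gb)) "diminished"
                   else "elevated")
}
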