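#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns on Euclidean beta
#' distances, cut to exactly `k` flat clusters. Used to ask whether replicate
#' samples resolve by individual (as they should for evCpGs) or by technical
#' batch (as for genetically driven control probes under batch effects).
#'
#' @param beta Probes x samples matrix (>= 1 probe, >= 2 samples).
#' @param k Number of flat clusters.
#' @param linkage `"average"` or `"complete"`.
#' @return A list with `tree` (an [stats::hclust] object) and `labels`
#'   (named integer cluster ids).
#' @export
hierarchical_clustering <- function(beta, k, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (ncol(beta) < 2) stop_("need at least 2 samples")
  if (!is_count(k) || k < 1 || k > ncol(beta))
    stop_("k must be an integer in [1, n_samples]")
  tree <- stats::hclust(stats::dist(t(beta), method = "euclidean"),
                        method = linkage)
  list(tree = tree, labels = stats::cutree(tree, k = k))
}

#' Score recovery of a known grouping by a flat clustering
#'
#' @param labels Cluster labels.
#' @param truth Ground-truth grouping, aligned with `labels`.
#' @return A list with `ari` (adjusted Rand index), `purity` (mean over
#'   clusters of the modal truth-class fraction) and `k`.
#' @export
replicate_recovery_score <- function(labels, truth) {
  if (length(labels) != length(truth)) stop_("labels and truth must align")
  tab <- table(labels, truth)
  purity <- sum(apply(tab, 1, max)) / length(labels)
  list(ari = mclust::adjustedRandIndex(labels, truth), purity = purity,
       k = length(unique(labels)))
}

#' Select genetically driven negative-control probes
#'
#' Returns the `n` most significant blood mQTL probes (smallest
#' `mqtl_rank`) among those present in the current matrix; ties at the
#' cut-off are broken by lexicographic probe id.
#'
#' @param manifest Data frame with `probe_id` and `mqtl_rank` (1 = most
#'   significant; `NA` = not an mQTL).
#' @param n Number of controls.
#' @param probes Probe ids available in the current matrix (default: all
#'   annotated).
#' @return Character vector of probe ids.
#' @export
select_negative_controls <- function(manifest, n, probes = manifest$probe_id) {
  if (!is_count(n) || n < 0) stop_("n must be a non-negative integer")
  if (n == 0) return(character())
  cand <- manifest[!is.na(manifest$mqtl_rank) & manifest$probe_id %in% probes, ]
  if (nrow(cand) < n)
    stop_("only ", nrow(cand), " annotated mQTL probes available, need ", n)
  cand <- cand[order(cand$mqtl_rank, cand$probe_id), ]
  cand$probe_id[seq_len(n)]
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on Euclidean beta distances. Coordinates are centred and
#' sign-fixed so the first nonzero loading of each dimension is positive.
#' Degenerate (all-equal) input returns zero coordinates with a flag.
#'
#' @param beta Probes x samples matrix (>= 3 samples).
#' @param k Embedding dimension.
#' @return Samples x k coordinate matrix; attribute `degenerate` is `TRUE`
#'   for all-equal input.
#' @export
classical_mds <- function(beta, k = 2) {
  if (ncol(beta) < 3) stop_("need at least 3 samples")
  d <- stats::dist(t(beta))
  if (all(d == 0)) {
    out <- matrix(0, ncol(beta), k, dimnames = list(colnames(beta), NULL))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- stats::cmdscale(d, k = k)
  if (ncol(out) < k)
    out <- cbind(out, matrix(0, nrow(out), k - ncol(out)))
  out <- sweep(out, 2, colMeans(out))
  for (j in seq_len(ncol(out))) {
    nz <- which(abs(out[, j]) > 1e-12)
    if (length(nz) && out[nz[1], j] < 0) out[, j] <- -out[, j]
  }
  attr(out, "degenerate") <- FALSE
  out
}
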