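# Readers and writers for the plain-text formats the pipeline consumes:
# beta matrices (TSV), sample sheets (CSV), probe manifests (TSV), region
# files (BED), and per-site WGBS count tables (TSV). Internal coordinates
# are 1-based inclusive everywhere; BED's 0-based half-open convention is
# converted once, at read time.

#' Read a beta-value matrix
#'
#' TSV with a header row of sample ids and probe ids in the first column.
#' Rows containing missing or out-of-range values are dropped; the count is
#' reported via a message and the `"dropped"` attribute.
#'
#' @param path File path.
#' @return Numeric probes x samples matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2) stop_("empty or malformed beta matrix: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_("duplicate probe ids in ", path)
  if (anyDuplicated(names(df)[-1])) stop_("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- apply(m, 1, function(x) anyNA(x) || any(x < 0 | x > 1))
  if (any(bad)) message("dropped ", sum(bad), " rows with missing/out-of-range values")
  out <- m[!bad, , drop = FALSE]
  attr(out, "dropped") <- sum(bad)
  out
}

#' Write a beta-value matrix
#'
#' Fixed 6-decimal formatting, so a write/read round trip is bit-stable.
#'
#' @param beta Probes x samples matrix.
#' @param path File path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta),
                   formatC(beta, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("probe_id", colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV requiring `sample_id`, `individual_id`, `family_id`; optional
#' columns (role, age, sex, replicate_id, timepoint, batch, tissue) pass
#' through. Families with other than two members are accepted here and
#' rejected by the twin-pairing step.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "individual_id", "family_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_("sample sheet missing required column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_("duplicated sample_id in ", path)
  df
}

#' Read a probe manifest
#'
#' TSV with `probe_id`, `chrom`, `pos`, a comma-separated `flags` column
#' (subset of low_quality, snp, cross_reactive, chrX, chrY; empty for
#' none), and any further annotation columns (e.g. `mqtl_rank`).
#'
#' @param path File path.
#' @return Data frame with `flags` parsed into a list-column.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop_("duplicate probe ids in manifest")
  if (any(df$pos < 1)) stop_("manifest positions must be >= 1")
  if ("flags" %in% names(df)) {
    fl <- ifelse(is.na(df$flags), "", df$flags)
    df$flags <- lapply(strsplit(fl, ",", fixed = TRUE), trimws)
    df$flags <- lapply(df$flags, function(f) f[nzchar(f)])
    bad <- setdiff(unlist(df$flags), FLAG_ORDER)
    if (length(bad)) stop_("unknown flags in manifest: ", paste(bad, collapse = ", "))
  } else df$flags <- replicate(nrow(df), character(), simplify = FALSE)
  df
}

# Sort and merge overlapping 1-based inclusive intervals.
merge_regions <- function(df) {
  df <- df[order(df$chrom, df$start), ]
  out <- merge_windows(df)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Read a BED region file
#'
#' BED3+ (0-based half-open); intervals are converted to the internal
#' 1-based inclusive convention, then sorted and merged per chromosome.
#' A line `chr1 0 10` therefore covers 1-based positions 1..10.
#'
#' @param path File path.
#' @return A `region_set` data frame `(chrom, start, end)`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 || is.na(suppressWarnings(as.numeric(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3]))))
      stop_("malformed BED line ", i, " in ", path)
    if (as.numeric(p[2]) >= as.numeric(p[3]))
      stop_("start >= end on BED line ", i, " in ", path)
  }
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  merge_regions(df)
}

#' Write a region set as BED
#'
#' Converts the internal 1-based inclusive intervals back to BED's 0-based
#' half-open convention.
#'
#' @param regions A `region_set`.
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(regions$chrom, format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-site WGBS count table
#'
#' Six columns: chrom, pos, strand (+/-), count_methylated, count_total,
#' beta. `dialect = "bedmethyl0"` accepts 0-based positions and shifts them
#' to the internal 1-based convention.
#'
#' @param path File path.
#' @param dialect `"tsv"` (1-based, default) or `"bedmethyl0"` (0-based).
#' @return Data frame sorted by `(chrom, pos)`.
#' @export
read_wgbs_sites <- function(path, dialect = c("tsv", "bedmethyl0")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "strand", "count_methylated", "count_total", "beta")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_("site table missing column(s): ", paste(miss, collapse = ", "))
  if (dialect == "bedmethyl0") df$pos <- df$pos + 1
  if (any(df$count_methylated > df$count_total | df$count_methylated < 0))
    stop_("invalid counts: need 0 <= methylated <= total")
  df[order(df$chrom, df$pos, df$strand), ]
}

#' Write a per-site WGBS count table
#'
#' @param sites Data frame as returned by [simulate_wgbs_pair()].
#' @param path File path.
#' @export
write_wgbs_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
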