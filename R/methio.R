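#' @import data.table
#' @importFrom stats pbinom rbinom rpois runif rnorm quantile var sd cor
#'   ks.test phyper median complete.cases setNames lm.fit model.matrix
#'   cor.test
#' @importFrom utils head modifyList packageVersion
NULL

# Column layout of the per-individual methylome table ("allc" dialect):
# chrom, pos (1-based), strand, context (3-mer), mc_count, total_count,
# methylated_flag. Only CG-context rows are expected after upstream filtering.
ALLC_COLS <- c("chrom", "pos", "strand", "context",
               "mc_count", "total_count", "methylated_flag")

CG_CONTEXTS <- c("CGA", "CGT", "CGC", "CGG")

#' Read a per-individual methylome table
#'
#' Parses an allc-style tab-separated file of per-site cytosine counts.
#' Coordinates are 1-based inclusive. Input must be position-sorted within
#' chromosome and satisfy `mc_count <= total_count`; violations are reported
#' with the offending line number.
#'
#' @param path Path to a tab-separated file with columns chrom, pos, strand,
#'   context, mc_count, total_count, methylated_flag (no header).
#' @param regions Optional `data.table` of BED-style regions (`chrom`,
#'   `start`, `end`; 0-based half-open). Sites outside all regions are
#'   dropped.
#' @return A `data.table` keyed by chrom and pos.
#' @export
read_methylome <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("methylome file not found: ", path)
  tbl <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = ALLC_COLS,
                           colClasses = list(character = c(1, 3, 4),
                                             integer = c(2, 5, 6, 7)))
  bad <- which(tbl$mc_count > tbl$total_count)
  if (length(bad)) {
    stop(sprintf("mc_count > total_count at line %d of %s", bad[1], path))
  }
  neg <- which(tbl$mc_count < 0L | tbl$total_count < 0L)
  if (length(neg)) stop(sprintf("negative count at line %d of %s", neg[1], path))
  # strictly increasing positions within each chromosome, in file order
  if (nrow(tbl) > 1) {
    same <- tbl$chrom[-1] == tbl$chrom[-nrow(tbl)]
    noninc <- which(same & diff(tbl$pos) <= 0)
    if (length(noninc)) {
      stop(sprintf("unsorted input: position %d (chrom %s) at line %d of %s",
                   tbl$pos[noninc[1] + 1], tbl$chrom[noninc[1] + 1],
                   noninc[1] + 1, path))
    }
  }
  if (!is.null(regions)) tbl <- filter_regions(tbl, regions)
  data.table::setkey(tbl, chrom, pos)
  tbl[]
}

# Restrict a methylome table to BED regions (0-based half-open on disk,
# converted to 1-based inclusive here).
filter_regions <- function(tbl, regions) {
  if (nrow(regions) == 0 || nrow(tbl) == 0) return(tbl[0])
  keep <- rep(FALSE, nrow(tbl))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (tbl$chrom == regions$chrom[i] &
                      tbl$pos >= regions$start[i] + 1L &
                      tbl$pos <= regions$end[i])
  }
  tbl[keep]
}

#' Write a methylome table in the allc dialect
#'
#' @param tbl A methylome `data.table` (see [read_methylome()]).
#' @param path Output path.
#' @export
write_methylome <- function(tbl, path) {
  out <- data.table::as.data.table(tbl)
  if (!"strand" %in% names(out)) out[, strand := "+"]
  if (!"methylated_flag" %in% names(out)) {
    out[, methylated_flag := as.integer(mc_count > 0L)]
  }
  data.table::fwrite(out[, ALLC_COLS, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Weighted methylation level
#'
#' Sum of methylated read counts over sum of total read counts across a set
#' of sites — the standard read-count-weighted average.
#'
#' @param mc Integer vector of methylated read counts.
#' @param total Integer vector of total read counts (same length).
#' @param min_total Minimum summed depth to report a level; below it, `NA`.
#' @return A fraction in \[0, 1\], or `NA_real_` if coverage is insufficient.
#' @export
weighted_methylation <- function(mc, total, min_total = 1L) {
  stopifnot(length(mc) == length(total))
  tt <- sum(as.numeric(total))
  if (tt < min_total || length(total) == 0L) return(NA_real_)
  sum(as.numeric(mc)) / tt
}

#' Call a binary methylation state from a methylation level
#'
#' Sites are classified as methylated or unmethylated with a 50% cut-off.
#' A level exactly at the cut-off is `ambiguous` (excluded downstream); a
#' site with fewer than `min_coverage` supporting reads is `missing`.
#'
#' @param level Methylation level(s) in \[0, 1\] (`NA` allowed).
#' @param total Total read count(s) supporting each level.
#' @param cutoff Classification cut-off, strictly inside (0, 1).
#' @param min_coverage Minimum reads to emit a call.
#' @return Character vector with values `"methylated"`, `"unmethylated"`,
#'   `"ambiguous"` or `"missing"`.
#' @export
call_state <- function(level, total, cutoff = 0.5, min_coverage = 3L) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie strictly inside (0, 1)")
  }
  n <- max(length(level), length(total))
  level <- rep_len(level, n)
  total <- rep_len(total, n)
  out <- rep("missing", n)
  ok <- !is.na(level) & !is.na(total) & total >= min_coverage
  out[ok & level > cutoff] <- "methylated"
  out[ok & level < cutoff] <- "unmethylated"
  out[ok & level == cutoff] <- "ambiguous"
  out
}

#' Binomial non-conversion filter for methylated read counts
#'
#' Incomplete bisulfite conversion makes unmethylated cytosines appear
#' methylated at a low background rate. Methylated counts that are not
#' significantly above that background (one-sided exact binomial test,
#' P(X >= mc | total, rate) >= alpha) are zeroed out; counts that pass are
#' returned unchanged. The filter is monotone in `mc` at fixed `total`.
#'
#' @param mc Methylated read counts (vector).
#' @param total Total read counts (vector, recycled).
#' @param rate Non-conversion rate (default 0.003, i.e. a 99.7% conversion
#'   rate measured on unmethylated control DNA).
#' @param alpha Significance level of the test.
#' @return Integer vector: `mc` where significant, otherwise 0.
#' @export
nonconversion_filter <- function(mc, total, rate = 0.003, alpha = 0.05) {
  n <- max(length(mc), length(total))
  mc <- rep_len(as.numeric(mc), n)
  total <- rep_len(as.numeric(total), n)
  stopifnot(all(mc <= total, na.rm = TRUE))
  # upper tail P(X >= mc) with X ~ Binom(total, rate)
  tail <- pbinom(mc - 1, total, rate, lower.tail = FALSE)
  out <- ifelse(mc > 0 & tail < alpha, mc, 0)
  as.integer(out)
}

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' Uses reads mapped to a genome known to be unmethylated (e.g. the
#' chloroplast): conversion = 1 - (methylated reads / total reads).
#'
#' @param control A methylome `data.table` of control sites (needs
#'   `mc_count`, `total_count`).
#' @return Conversion rate in \[0, 1\], or `NA_real_` with zero total reads.
#' @export
estimate_conversion <- function(control) {
  tt <- sum(as.numeric(control$total_count))
  if (tt == 0) return(NA_real_)
  1 - sum(as.numeric(control$mc_count)) / tt
}
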