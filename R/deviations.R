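#' Eligibility of (site, individual) cells for gain or loss estimation
#'
#' Somatic gains are estimated only from cells whose inherited diplotype is
#' unmethylated on both alleles; losses only from cells inherited methylated
#' on both alleles. Concretely, for gains: class-00 sites in all
#' individuals; class-01 sites with an unmethylated northern allele in NN
#' individuals only (and symmetrically for an unmethylated southern allele in
#' SS individuals). Individuals heterozygous for methylation state (ancestry
#' NS at a class-01 site) are never used. Losses mirror this for methylated
#' alleles. Ambiguous sites are never eligible.
#'
#' @param f1 Output of [infer_f1_epigenotype()] (needs n_state, s_state,
#'   class).
#' @param site_ancestry Integer matrix (sites x individuals) of N-allele
#'   counts (`NA` = unknown).
#' @param type `"gain"` or `"loss"`.
#' @return Logical matrix (sites x individuals).
#' @export
eligible_sites <- function(f1, site_ancestry, type = c("gain", "loss")) {
  type <- match.arg(type)
  want <- if (type == "gain") "unmethylated" else "methylated"
  n_ok <- f1$n_state == want
  s_ok <- f1$s_state == want
  both <- n_ok & s_ok            # class 00 (gains) / 11 (losses)
  het_n <- n_ok & !s_ok & f1$class == "01"
  het_s <- s_ok & !n_ok & f1$class == "01"
  k <- site_ancestry
  elig <- (both & !is.na(k)) |
    (het_n & !is.na(k) & k == 2L) |
    (het_s & !is.na(k) & k == 0L)
  elig
}

#' Compute the region-by-individual deviation matrix
#'
#' Gains and losses are read-count-weighted averages over eligible sites:
#' gain = sum(mc) / sum(total); loss = 1 - sum(mc) / sum(total). Regions are
#' genes or non-overlapping 500-kb windows. For gains, methylated counts
#' should first be passed through [nonconversion_filter()]; losses use raw
#' counts (over-conversion has no usable rate estimate).
#'
#' @param mc,tot Count matrices (sites x individuals). For gains, pass
#'   filtered `mc`.
#' @param eligible Logical matrix from [eligible_sites()].
#' @param region Factor/character vector assigning each site to a region
#'   (`NA` sites are dropped).
#' @param type `"gain"` or `"loss"`.
#' @param individuals Optional individual ids (defaults to column index).
#' @return Long `data.table`: region, individual, type, deviation, mc_sum,
#'   total_sum, n_sites. Cells with zero eligible coverage are absent.
#' @export
compute_deviations <- function(mc, tot, eligible, region,
                               type = c("gain", "loss"),
                               individuals = NULL) {
  type <- match.arg(type)
  stopifnot(length(region) == nrow(mc))
  if (is.null(individuals)) individuals <- sprintf("ind_%04d", seq_len(ncol(mc)))
  keep <- !is.na(region)
  regs <- factor(region[keep])
  mcz <- mc[keep, , drop = FALSE] * eligible[keep, , drop = FALSE]
  totz <- tot[keep, , drop = FALSE] * eligible[keep, , drop = FALSE]
  agg_mc <- rowsum(mcz, regs)
  agg_tot <- rowsum(totz, regs)
  agg_n <- rowsum((totz > 0) + 0L, regs)
  dt <- data.table::data.table(
    region = rep(rownames(agg_mc), ncol(mcz)),
    individual = rep(individuals, each = nrow(agg_mc)),
    type = type,
    mc_sum = as.vector(agg_mc),
    total_sum = as.vector(agg_tot),
    n_sites = as.vector(agg_n))
  dt <- dt[total_sum > 0]
  ratio <- dt$mc_sum / dt$total_sum
  data.table::set(dt, j = "deviation",
                  value = if (type == "gain") ratio else 1 - ratio)
  dt[]
}

#' Stratified deviation summary with bootstrap confidence intervals
#'
#' Computes read-weighted mean deviations per stratum (e.g. sequence context,
#' pericentromere status, local ancestry, parental differential status,
#' chromatin cluster, temperature) and returns bootstrap replicates obtained
#' by resampling individuals, from which ratio contrasts with percentile CIs
#' can be formed via [stratum_ratio()].
#'
#' @param mc,tot Count matrices (sites x individuals); pass filtered `mc`
#'   for gains.
#' @param eligible Logical eligibility matrix.
#' @param strata Either a per-site vector (length nrow) or a cell-level
#'   matrix (same dim as `mc`) of stratum labels; `NA` cells are dropped.
#' @param type `"gain"` or `"loss"`.
#' @param n_boot Bootstrap resamples over individuals.
#' @param seed Optional RNG seed for the bootstrap.
#' @return List of class `stratified_summary`: `summary` (`data.table`
#'   stratum, deviation, mc_sum, total_sum), `boot` (n_boot x strata matrix
#'   of replicate means), `type`.
#' @export
stratified_summary <- function(mc, tot, eligible, strata,
                               type = c("gain", "loss"),
                               n_boot = 1000L, seed = NULL) {
  type <- match.arg(type)
  n_ind <- ncol(mc)
  cell_strata <- if (is.matrix(strata)) strata
    else matrix(strata, nrow(mc), n_ind)
  levs <- sort(unique(as.vector(cell_strata[!is.na(cell_strata)])))
  # per-individual per-stratum count sums; bootstrap then only resamples rows
  S_mc <- matrix(0, n_ind, length(levs), dimnames = list(NULL, levs))
  S_tot <- matrix(0, n_ind, length(levs), dimnames = list(NULL, levs))
  for (si in seq_along(levs)) {
    sel <- eligible & !is.na(cell_strata) & cell_strata == levs[si]
    S_mc[, si] <- colSums(mc * sel)
    S_tot[, si] <- colSums(tot * sel)
  }
  dev_from_sums <- function(m, t) {
    r <- ifelse(t > 0, m / t, NA_real_)
    if (type == "loss") 1 - r else r
  }
  obs <- dev_from_sums(colSums(S_mc), colSums(S_tot))
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(levs), dimnames = list(NULL, levs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_ind, replace = TRUE)
    boot[b, ] <- dev_from_sums(colSums(S_mc[idx, , drop = FALSE]),
                               colSums(S_tot[idx, , drop = FALSE]))
  }
  res <- list(summary = data.table::data.table(stratum = levs,
                                               deviation = obs,
                                               mc_sum = colSums(S_mc),
                                               total_sum = colSums(S_tot)),
              boot = boot, type = type)
  class(res) <- "stratified_summary"
  res
}

#' Ratio contrast between strata with a bootstrap CI
#'
#' @param ss A `stratified_summary`.
#' @param numerator,denominator Stratum labels. Either may be a vector; a
#'   vector denominator is combined as the unweighted mean of its stratum
#'   means (e.g. "CGT vs mean of the other three contexts").
#' @param conf Confidence level for the percentile interval.
#' @return List: `ratio`, `ci` (length 2), `excess_pct` (100 * (ratio - 1))
#'   with its own `excess_ci`.
#' @export
stratum_ratio <- function(ss, numerator, denominator, conf = 0.95) {
  pick <- function(x, labs) {
    if (length(labs) == 1L) x[, labs] else rowMeans(x[, labs, drop = FALSE])
  }
  obs <- setNames(ss$summary$deviation, ss$summary$stratum)
  obs_m <- t(as.matrix(obs))
  ratio <- pick(obs_m, numerator) / pick(obs_m, denominator)
  br <- pick(ss$boot, numerator) / pick(ss$boot, denominator)
  a <- (1 - conf) / 2
  ci <- unname(quantile(br, c(a, 1 - a), na.rm = TRUE))
  list(ratio = unname(ratio), ci = ci,
       excess_pct = unname(100 * (ratio - 1)), excess_ci = 100 * (ci - 1))
}

#' Deviation profile by distance to the nearest methylated CG
#'
#' For each focal site the distance to the nearest parentally methylated CG
#' site on the same chromosome (excluding itself) is computed, and per-site
#' deviations are summarised in distance bins (median and central 90% band).
#'
#' @param sites `data.table` with chrom, pos and a per-site `deviation`
#'   column (mean over individuals).
#' @param methylated `data.table` of methylated-site coordinates (chrom,
#'   pos).
#' @param max_bp Maximum distance retained.
#' @param bins Number of equal-width distance bins.
#' @return `data.table`: bin_mid, n, median, q05, q95.
#' @export
distance_profile <- function(sites, methylated, max_bp = 1000L, bins = 20L) {
  sites <- data.table::as.data.table(sites)
  out <- list()
  for (ch in unique(sites$chrom)) {
    mp <- sort(methylated[chrom == ch]$pos)
    sp <- sites[chrom == ch]
    if (length(mp) < 1L || nrow(sp) < 2L) next
    i <- findInterval(sp$pos, mp)          # mp[i] <= pos
    exact <- i >= 1L & mp[pmax(i, 1L)] == sp$pos
    li <- ifelse(exact, i - 1L, i)         # skip the site itself
    dl <- ifelse(li >= 1L, sp$pos - mp[pmax(li, 1L)], Inf)
    dr <- ifelse(i < length(mp), mp[pmin(i + 1L, length(mp))] - sp$pos, Inf)
    d <- pmin(dl, dr)
    out[[ch]] <- data.table::data.table(dist = d, deviation = sp$deviation)
  }
  if (!length(out)) {
    return(data.table::data.table(bin_mid = numeric(), n = integer(),
                                  median = numeric(), q05 = numeric(),
                                  q95 = numeric()))
  }
  dd <- data.table::rbindlist(out)[is.finite(dist) & dist <= max_bp]
  w <- max_bp / bins
  dd[, bin := pmin(floor(dist / w), bins - 1)]
  prof <- dd[, .(n = .N, median = median(deviation),
                 q05 = quantile(deviation, 0.05),
                 q95 = quantile(deviation, 0.95)),
             by = .(bin_mid = (bin + 0.5) * w)][order(bin_mid)]
  prof[]
}

#' Rank correlation between allelic deviation differences and parental
#' methylation differences
#'
#' Tests for cis-acting factors: per gene, the difference in mean deviation
#' between NN- and SS-ancestry individuals is correlated (Spearman) with the
#' parental difference in gene-body methylation.
#'
#' @param dev_n,dev_s Per-gene mean deviations in NN and SS individuals.
#' @param gbm_n,gbm_s Per-gene parental methylation levels.
#' @return List: `rho`, `p_value`, `n`.
#' @export
allelic_difference_correlation <- function(dev_n, dev_s, gbm_n, gbm_s) {
  ok <- complete.cases(dev_n, dev_s, gbm_n, gbm_s)
  if (sum(ok) < 10L) {
    stop("fewer than 10 genes with both strata non-missing (", sum(ok), ")")
  }
  ct <- suppressWarnings(cor.test(dev_n[ok] - dev_s[ok],
                                  gbm_n[ok] - gbm_s[ok],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Genomic autocorrelation of window deviations
#'
#' Pearson correlation of window mean deviations at increasing genomic lags;
#' chromosomes are never bridged.
#'
#' @param windows `data.table` with chrom, start and a `value` column,
#'   genome-ordered.
#' @param max_lag Maximum lag in windows.
#' @return `data.table`: lag, correlation, n_pairs.
#' @export
genome_autocorrelation <- function(windows, max_lag = 10L) {
  windows <- data.table::as.data.table(windows)[order(chrom, start)]
  rows <- list()
  for (lag in seq_len(max_lag)) {
    xs <- list(); ys <- list()
    for (ch in unique(windows$chrom)) {
      v <- windows[chrom == ch]$value
      if (length(v) > lag) {
        xs[[ch]] <- v[seq_len(length(v) - lag)]
        ys[[ch]] <- v[-seq_len(lag)]
      }
    }
    x <- unlist(xs); y <- unlist(ys)
    if (is.null(x) || length(x) < 3L) next
    ok <- complete.cases(x, y)
    if (sum(ok) >= 3L) {
      rows[[lag]] <- data.table::data.table(lag = lag,
                                            correlation = cor(x[ok], y[ok]),
                                            n_pairs = sum(ok))
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(lag = integer(), correlation = numeric(),
                                  n_pairs = integer()))
  }
  data.table::rbindlist(rows)
}

#' Assign sites to 500-kb windows
#'
#' @param sites Site table with chrom, pos.
#' @param window_bp Window width (default 500 kb, tiled from position 1).
#' @return Character vector of window labels, parallel to `sites`.
#' @export
assign_windows <- function(sites, window_bp = 500000L) {
  start <- (sites$pos - 1L) %/% as.integer(window_bp) * as.integer(window_bp)
  sprintf("%s:%d-%d", sites$chrom, start, start + as.integer(window_bp))
}
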