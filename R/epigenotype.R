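F1_CLASSES <- c("00", "01", "11", "ambiguous")

#' Infer a grand-parental methylation state from replicate methylomes
#'
#' Read counts are pooled across replicate individuals of one inbred line
#' (count-weighted), and the pooled level is classified with the 50% cut-off.
#' Because the line is inbred, the pooled call estimates the methylation
#' state of the common grand-parental individual.
#'
#' @param mc,tot Matrices (sites x replicates) of methylated/total counts.
#' @param cutoff State-call cut-off.
#' @param min_coverage Minimum pooled reads to emit a call.
#' @return List: `state` (character per site), `level` (pooled level),
#'   `total` (pooled depth).
#' @export
infer_parental_state <- function(mc, tot, cutoff = 0.5, min_coverage = 3L) {
  mc <- as.matrix(mc); tot <- as.matrix(tot)
  if (!any(tot > 0)) stop("no covered sites shared across replicates")
  pooled_mc <- rowSums(mc)
  pooled_tot <- rowSums(tot)
  level <- ifelse(pooled_tot > 0, pooled_mc / pooled_tot, NA_real_)
  state <- call_state(level, pooled_tot, cutoff, min_coverage)
  list(state = state, level = level, total = pooled_tot)
}

#' Interpolate per-site local ancestry from the marker grid
#'
#' Each CG site takes the MAP ancestry of its nearest marker. Sites whose two
#' flanking markers disagree are set missing (conservative: ancestry there is
#' uncertain because a crossover lies nearby).
#'
#' @param marker_state Matrix (markers x individuals) of MAP states
#'   (`"NN"`/`"NS"`/`"SS"`).
#' @param map Marker map `data.table` (marker, chrom, bp, cM).
#' @param sites Site table with columns chrom, pos.
#' @return Integer matrix (sites x individuals) of N-allele counts
#'   (2 = NN, 1 = NS, 0 = SS, `NA` = ambiguous).
#' @export
ancestry_at_sites <- function(marker_state, map, sites) {
  n_ind <- ncol(marker_state)
  out <- matrix(NA_integer_, nrow(sites), n_ind)
  code <- matrix(match(marker_state, ANCESTRY_STATES), nrow(map), n_ind)
  n_alleles <- c(2L, 1L, 0L)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    mi <- which(map$chrom == ch)
    if (!length(mi)) next
    mbp <- map$bp[mi]
    pos <- sites$pos[si]
    left <- findInterval(pos, mbp)
    right <- pmin(left + 1L, length(mi))
    left <- pmax(left, 1L)
    nearest <- ifelse(abs(pos - mbp[left]) <= abs(mbp[right] - pos),
                      left, right)
    for (j in seq_len(n_ind)) {
      sl <- code[mi[left], j]
      sr <- code[mi[right], j]
      v <- n_alleles[code[mi[nearest], j]]
      v[sl != sr] <- NA_integer_
      out[si, j] <- v
    }
  }
  out
}

#' Infer the F1 per-allele epigenotype from F2 segregation
#'
#' The northern-allele methylation state at each site is called from read
#' counts pooled across F2 individuals with homozygous NN local ancestry; the
#' southern allele likewise from SS individuals. Heterozygous (NS)
#' individuals are not used. A site with fewer than `min_individuals`
#' covered individuals in a homozygous class gets a missing allele call.
#'
#' @param mc,tot Matrices (sites x F2 individuals) of read counts.
#' @param site_ancestry Integer matrix from [ancestry_at_sites()] (or
#'   simulation truth): N-allele counts, `NA` = unknown.
#' @param cutoff State-call cut-off.
#' @param min_individuals Minimum covered individuals per homozygous class.
#' @param min_coverage Minimum pooled reads for a call.
#' @return `data.table`: n_state, s_state, class (`"00"`, `"01"`, `"11"`,
#'   `"ambiguous"`), n_level, s_level, n_ind_nn, n_ind_ss.
#' @export
infer_f1_epigenotype <- function(mc, tot, site_ancestry, cutoff = 0.5,
                                 min_individuals = 10L, min_coverage = 3L) {
  stopifnot(all(dim(mc) == dim(tot)), all(dim(mc) == dim(site_ancestry)))
  pool <- function(k_alleles) {
    sel <- !is.na(site_ancestry) & site_ancestry == k_alleles
    pm <- rowSums(mc * sel)
    pt <- rowSums(tot * sel)
    nind <- rowSums(sel & tot > 0L)
    level <- ifelse(pt > 0, pm / pt, NA_real_)
    state <- call_state(level, pt, cutoff, min_coverage)
    state[nind < min_individuals] <- "missing"
    list(state = state, level = level, nind = nind)
  }
  n_pool <- pool(2L)
  s_pool <- pool(0L)
  cls <- classify_f1(n_pool$state, s_pool$state)
  data.table::data.table(n_state = n_pool$state, s_state = s_pool$state,
                         class = cls,
                         n_level = n_pool$level, s_level = s_pool$level,
                         n_ind_nn = n_pool$nind, n_ind_ss = s_pool$nind)
}

#' Classify an F1 site from its two allele states
#'
#' `"00"` both alleles unmethylated, `"11"` both methylated, `"01"`
#' heterozygous for methylation state; any ambiguous or missing allele makes
#' the site `"ambiguous"`.
#'
#' @param n_state,s_state Character vectors of allele state calls.
#' @return Character vector over `c("00", "01", "11", "ambiguous")`.
#' @export
classify_f1 <- function(n_state, s_state) {
  out <- rep("ambiguous", length(n_state))
  nm <- n_state == "methylated"; nu <- n_state == "unmethylated"
  sm <- s_state == "methylated"; su <- s_state == "unmethylated"
  out[nu & su] <- "00"
  out[nm & sm] <- "11"
  out[(nm & su) | (nu & sm)] <- "01"
  out
}

#' Mendelian segregation check of inferred epigenotypes
#'
#' For heterozygous (01) sites, individuals of NS ancestry carry one
#' methylated and one unmethylated allele and are expected to show ~50%
#' methylation; homozygous classes should sit near 0 (00) and 1 (11). Returns
#' pooled weighted levels per (class x ancestry) cell.
#'
#' @param mc,tot Count matrices (sites x individuals).
#' @param f1 Output of [infer_f1_epigenotype()].
#' @param site_ancestry Integer matrix of N-allele counts.
#' @return `data.table`: class, ancestry, level, n_sites, total_reads.
#' @export
check_mendelian <- function(mc, tot, f1, site_ancestry) {
  rows <- list()
  for (cl in c("00", "01", "11")) {
    csel <- f1$class == cl
    for (k in c(2L, 1L, 0L)) {
      sel <- csel & !is.na(site_ancestry) & site_ancestry == k
      tt <- sum(as.numeric(tot[sel]))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        class = cl, ancestry = ANCESTRY_STATES[3L - k],
        level = if (tt > 0) sum(as.numeric(mc[sel])) / tt else NA_real_,
        n_sites = sum(csel), total_reads = tt)
    }
  }
  data.table::rbindlist(rows)
}

#' Exclude genes with substantial non-CG methylation
#'
#' Gene-body methylation is defined by CG-only methylation; genes showing
#' elevated CHG or CHH methylation in either parental line are excluded.
#' Levels are z-scored per line and context, and genes with any z > 2 are
#' dropped. A context with zero variance yields no exclusions.
#'
#' @param gene_levels `data.table` with columns gene, line, mCHG, mCHH.
#' @param z_max Exclusion threshold in standard deviations.
#' @return List: `retained` (gene ids), `excluded` (`data.table` gene,
#'   line, context, z).
#' @export
filter_gbm_genes <- function(gene_levels, z_max = 2) {
  gl <- data.table::as.data.table(gene_levels)
  excl <- list()
  for (ln in unique(gl$line)) {
    for (ctx in c("mCHG", "mCHH")) {
      v <- gl[line == ln][[ctx]]
      s <- sd(v)
      if (is.na(s) || s == 0) next
      z <- (v - mean(v)) / s
      bad <- which(z > z_max)
      if (length(bad)) {
        excl[[length(excl) + 1L]] <- data.table::data.table(
          gene = gl[line == ln]$gene[bad], line = ln, context = ctx,
          z = z[bad])
      }
    }
  }
  excluded <- if (length(excl)) data.table::rbindlist(excl) else
    data.table::data.table(gene = character(), line = character(),
                           context = character(), z = numeric())
  list(retained = setdiff(unique(gl$gene), excluded$gene),
       excluded = excluded)
}
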