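#' Marginal deviation rates
#'
#' From a sites-by-individuals matrix of per-cell deviation fractions
#' `x[i, j] = f_ij / n_ij` (non-ancestral over total reads), computes the
#' per-site mean over individuals, the per-individual mean over sites, and
#' the grand mean. Missing cells (no reads) are excluded with per-row /
#' per-column denominators.
#'
#' @param x Numeric matrix (sites x individuals), `NA` where undefined.
#' @return List of class `marginal_rates`: `site_mean`, `ind_mean`, `grand`,
#'   `M`, `N`.
#' @export
marginal_rates <- function(x) {
  stopifnot(is.matrix(x))
  obs <- !is.na(x)
  empty_row <- which(rowSums(obs) == 0)
  if (length(empty_row)) stop("site(s) with no observed individuals: row ",
                              empty_row[1])
  empty_col <- which(colSums(obs) == 0)
  if (length(empty_col)) stop("individual(s) with no observed sites: column ",
                              empty_col[1])
  site_mean <- rowMeans(x, na.rm = TRUE)
  ind_mean <- colMeans(x, na.rm = TRUE)
  structure(list(site_mean = site_mean, ind_mean = ind_mean,
                 grand = mean(x, na.rm = TRUE),
                 M = nrow(x), N = ncol(x)),
            class = "marginal_rates")
}

#' Simulate deviation matrices under the binomial independence null
#'
#' The null model states that deviations arise independently in each cell
#' (read/cell-level mutations with site- and individual-specific
#' probabilities): reads are redrawn as Binomial(n_ij, p_ij) with
#' `p_ij = site_mean_i + ind_mean_j`, clipped to \[0, 1\]. The observed
#' missingness pattern of `depth` is preserved.
#'
#' @param depth Integer matrix of read depths n_ij (`NA` or 0 = missing).
#' @param rates A [marginal_rates()] object.
#' @param n_reps Number of simulated matrices.
#' @param seed Optional RNG seed.
#' @return List of `n_reps` deviation matrices (same dim as `depth`).
#' @export
simulate_null <- function(depth, rates, n_reps = 200L, seed = NULL) {
  stopifnot(nrow(depth) == rates$M, ncol(depth) == rates$N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- outer(rates$site_mean, rates$ind_mean, `+`)
  p <- pmin(pmax(p, 0), 1)
  n_vec <- as.vector(depth)
  ok <- !is.na(n_vec) & n_vec > 0
  lapply(seq_len(n_reps), function(r) {
    f <- rep(NA_real_, length(n_vec))
    f[ok] <- rbinom(sum(ok), n_vec[ok], as.vector(p)[ok])
    matrix(f / n_vec, nrow(depth), ncol(depth))
  })
}

#' Compare between-individual variance with the binomial null
#'
#' For each site, the variance of deviations across individuals is compared
#' with its distribution under [simulate_null()]. Clonal/sectored
#' epimutations within individuals would inflate this variance; shared
#' (non-independent) deviations across individuals deflate it. The summary
#' reports the fraction of sites whose observed variance exceeds the null
#' 97.5% quantile or falls below the null 2.5% quantile, plus a
#' Kolmogorov-Smirnov statistic between the observed and pooled null
#' variance distributions.
#'
#' @param x Observed deviation matrix (sites x individuals).
#' @param sims Output of [simulate_null()].
#' @return List: `per_site` (`data.table` site, var_data, null_mean,
#'   null_lo, null_hi), `summary` (list above_frac, below_frac, ks,
#'   n_sites_used, n_excluded, degenerate).
#' @export
variance_comparison <- function(x, sims) {
  n_obs <- rowSums(!is.na(x))
  use <- n_obs >= 2L
  row_var <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    k <- rowSums(!is.na(m))
    rowSums((m - mu)^2, na.rm = TRUE) / pmax(k - 1, 1)
  }
  vd <- row_var(x)[use]
  vnull <- vapply(sims, function(s) row_var(s)[use], numeric(sum(use)))
  if (sum(use) == 1L) vnull <- matrix(vnull, nrow = 1L)
  lo <- apply(vnull, 1, quantile, 0.025, na.rm = TRUE)
  hi <- apply(vnull, 1, quantile, 0.975, na.rm = TRUE)
  per_site <- data.table::data.table(site = which(use), var_data = vd,
                                     null_mean = rowMeans(vnull),
                                     null_lo = lo, null_hi = hi)
  degenerate <- ncol(x) < 2L || sum(use) == 0L
  summary <- list(
    above_frac = if (degenerate) NA_real_ else mean(vd > hi),
    below_frac = if (degenerate) NA_real_ else mean(vd < lo),
    ks = if (degenerate) NA_real_ else
      suppressWarnings(ks.test(vd, as.vector(vnull))$statistic),
    n_sites_used = sum(use), n_excluded = sum(!use),
    degenerate = degenerate)
  list(per_site = per_site, summary = summary)
}
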