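#' Filter sites suitable for epimutation-rate estimation
#'
#' Transgenerational rate estimation is sensitive to sites that are not
#' stably called: residual grand-parental heterozygosity, cryptic copy
#' number, or hyper-variable somatic behaviour all produce intermediate
#' methylation. Sites are retained only if their mean somatic gain is below
#' `gain_max` and mean somatic loss below `loss_max`, and both generations
#' have an unambiguous state call.
#'
#' @param gain_mean,loss_mean Per-site mean somatic deviations (`NA` allowed;
#'   an `NA` mean does not trigger the corresponding bound).
#' @param gp_state,f1_state Character state calls for the grand-parental and
#'   F1 generation (`"methylated"` / `"unmethylated"` / `"ambiguous"` /
#'   `"missing"`).
#' @param gain_max,loss_max Stability bounds on mean somatic deviations.
#' @return List: `retained` (logical vector), `reasons` (`data.table` of
#'   removal counts by reason).
#' @export
filter_stable_sites <- function(gain_mean, loss_mean, gp_state, f1_state,
                                gain_max = 0.2, loss_max = 0.35) {
  n <- length(gp_state)
  gain_mean <- rep_len(gain_mean, n)
  loss_mean <- rep_len(loss_mean, n)
  callable <- c("methylated", "unmethylated")
  bad_gain <- !is.na(gain_mean) & gain_mean >= gain_max
  bad_loss <- !is.na(loss_mean) & loss_mean >= loss_max
  bad_gp <- !gp_state %in% callable
  bad_f1 <- !f1_state %in% callable
  retained <- !(bad_gain | bad_loss | bad_gp | bad_f1)
  if (!any(retained)) warning("no sites retained by the stability filter")
  reasons <- data.table::data.table(
    reason = c("gain_bound", "loss_bound", "grandparent_state", "f1_state"),
    n_removed = c(sum(bad_gain), sum(bad_loss), sum(bad_gp), sum(bad_f1)))
  list(retained = retained, reasons = reasons)
}

#' Estimate per-generation transgenerational epimutation rates
#'
#' Compares the inferred grand-parental methylation state with the inferred
#' state of the corresponding F1 allele. Any discordance reflects a state
#' change somewhere along two generations of inheritance, so counts are
#' normalised by `generations = 2`. Gains and losses are normalised by the
#' number of informative sites at risk of that change (unmethylated and
#' methylated in the grandparent, respectively).
#'
#' @param gp_state,f1_state Character state vectors (one per site).
#' @param retained Logical vector from [filter_stable_sites()] (default all).
#' @param generations Number of generations separating the two calls.
#' @param lineage Label stored in the output.
#' @return List of class `epimutation_estimate`: lineage, n_informative,
#'   n_unmethylated_gp, n_methylated_gp, n_gains, n_losses, gain_rate,
#'   loss_rate, generations.
#' @export
estimate_rates <- function(gp_state, f1_state, retained = NULL,
                           generations = 2L, lineage = "N") {
  n <- length(gp_state)
  if (is.null(retained)) retained <- rep(TRUE, n)
  callable <- c("methylated", "unmethylated")
  inf <- retained & gp_state %in% callable & f1_state %in% callable
  if (!any(inf)) stop("zero informative sites for lineage ", lineage)
  gp_m <- gp_state == "methylated"
  f1_m <- f1_state == "methylated"
  n_gains <- sum(inf & !gp_m & f1_m)
  n_losses <- sum(inf & gp_m & !f1_m)
  n_u <- sum(inf & !gp_m)
  n_m <- sum(inf & gp_m)
  structure(list(lineage = lineage, n_informative = sum(inf),
                 n_unmethylated_gp = n_u, n_methylated_gp = n_m,
                 n_gains = n_gains, n_losses = n_losses,
                 gain_rate = if (n_u > 0) n_gains / (n_u * generations)
                 else NA_real_,
                 loss_rate = if (n_m > 0) n_losses / (n_m * generations)
                 else NA_real_,
                 generations = generations),
            class = "epimutation_estimate")
}

#' Overlap of epimutated sites between lineages or crosses
#'
#' Under independent random epimutation the expected overlap of two site
#' sets is `|A| |B| / U`. Reports the observed overlap, that expectation,
#' their ratio, and a hypergeometric enrichment p-value.
#'
#' @param a,b Integer or character vectors of epimutated site identifiers.
#' @param universe_size Number of sites both lineages could have mutated.
#' @return List: observed, expected, ratio, p_value.
#' @export
overlap_between_lineages <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (universe_size < max(length(a), length(b))) {
    stop("universe smaller than a site set (", universe_size, " < ",
         max(length(a), length(b)), ")")
  }
  obs <- length(intersect(a, b))
  expd <- length(a) * length(b) / universe_size
  p <- phyper(obs - 1, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  list(observed = obs, expected = expd,
       ratio = if (expd > 0) obs / expd else NA_real_, p_value = p)
}

#' Epimutation rates stratified by parental-differential status
#'
#' @param gp_state,f1_state State vectors as in [estimate_rates()].
#' @param differential Logical vector: parental states differ at the site.
#' @param retained Logical stability filter.
#' @param generations Generations separating the calls.
#' @param lineage Label.
#' @return List: `estimates` (`data.table` stratum, n_informative,
#'   gain_rate, loss_rate), `gain_fold`, `loss_fold` (diff / same; `NA` when
#'   a stratum is empty).
#' @export
rates_by_site_class <- function(gp_state, f1_state, differential,
                                retained = NULL, generations = 2L,
                                lineage = "N") {
  if (is.null(retained)) retained <- rep(TRUE, length(gp_state))
  strata <- list(diff = differential, same = !differential)
  rows <- list()
  est <- list()
  for (nm in names(strata)) {
    sel <- retained & strata[[nm]]
    if (!any(sel)) next
    e <- tryCatch(estimate_rates(gp_state[sel], f1_state[sel],
                                 generations = generations,
                                 lineage = lineage),
                  error = function(err) NULL)
    if (is.null(e)) next
    est[[nm]] <- e
    rows[[nm]] <- data.table::data.table(
      stratum = nm, n_informative = e$n_informative,
      gain_rate = e$gain_rate, loss_rate = e$loss_rate)
  }
  tab <- data.table::rbindlist(rows)
  fold <- function(field) {
    if (!all(c("diff", "same") %in% names(est))) return(NA_real_)
    d <- est$diff[[field]]; s <- est$same[[field]]
    if (is.na(d) || is.na(s) || s == 0) NA_real_ else d / s
  }
  list(estimates = tab, gain_fold = fold("gain_rate"),
       loss_fold = fold("loss_rate"))
}
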