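#' Simulation-based parameter recovery
#'
#' The headline quantities this pipeline estimates (population-mean somatic
#' gains and losses, stratified fold effects, transgenerational epimutation
#' rates, QTL variance explained) cannot be validated on the original
#' sequencing data, so validation is by parameter recovery: a scenario is
#' simulated with a known truth, the full estimation path is run on it, and
#' the estimate is compared with the planted value. These helpers define the
#' standard recovery frames; they are used both by the test suite and by
#' `scripts/acceptance.R`.
#'
#' @name recovery
NULL

# sim_config with every modifier fold neutralised; frames then switch on the
# single effect they target.
neutral_config <- function(...) {
  base <- list(gain_fold_pericentromere = 1, loss_fold_cgt = 1,
               gain_fold_nn_vs_ss = 1, loss_fold_ss_vs_nn = 1,
               gain_fold_differential = 1, loss_fold_differential = 1,
               epimutation_gain_rate = 0, epimutation_loss_rate = 0)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# shared estimation path: HMM ancestry (or truth), F1 epigenotype,
# eligibility, non-conversion-filtered counts for gains
recovery_estimate <- function(scen, type, use_hmm = TRUE,
                              min_individuals = 10L) {
  rd <- scen$reads
  if (use_hmm) {
    anc <- infer_ancestry_all(rd$marker_n, rd$marker_s, scen$truth$map)
    sa <- ancestry_at_sites(anc$map_state, scen$truth$map, scen$truth$sites)
  } else {
    sa <- scen$truth$site_n_alleles
  }
  f1 <- infer_f1_epigenotype(rd$mc, rd$tot, sa,
                             min_individuals = min_individuals)
  elig <- eligible_sites(f1, sa, type)
  mc_use <- if (type == "gain") {
    matrix(nonconversion_filter(rd$mc, rd$tot), nrow(rd$mc))
  } else rd$mc
  list(f1 = f1, site_ancestry = sa, eligible = elig, mc = mc_use,
       tot = rd$tot)
}

#' Recover the population-mean somatic deviation
#'
#' Simulates an F2 population whose per-read loss (or gain) probability is a
#' known constant, runs ancestry inference, epigenotype inference and
#' deviation estimation, and returns the genome-wide read-weighted mean
#' deviation in percent. Losses use the 7.3% genome-wide mean as planted
#' truth; gains 0.09% (with the non-conversion filter active and
#' non-conversion set to zero, since gains this small are otherwise swamped
#' at shallow coverage).
#'
#' @param type `"loss"` or `"gain"`.
#' @param seed Integer seed.
#' @param n_f2 Number of F2 individuals.
#' @param n_sites Number of CG sites (all inherited in the state at risk).
#' @param coverage Mean read depth.
#' @return List: `value` (percent), `truth` (percent), `n` (site-individual
#'   observations).
#' @export
recovery_mean_deviation <- function(type = c("loss", "gain"), seed = 1L,
                                    n_f2 = 200L, n_sites = 20000L,
                                    coverage = 5) {
  type <- match.arg(type)
  cfg <- neutral_config(
    n_sites = n_sites, n_f2 = n_f2, coverage_mean = coverage,
    frac_methylated_any_parent = if (type == "loss") 1 else 0,
    frac_differential = 0,
    gain_rate_base = if (type == "gain") 0.0009 else 0,
    loss_rate_base = if (type == "loss") 0.073 else 0,
    nonconversion_rate = if (type == "gain") 0 else 0.003,
    marker_spacing_bp = 60000L, marker_coverage_mean = 1,
    seed = seed)
  scen <- simulate_scenario(cfg)
  est <- recovery_estimate(scen, type, use_hmm = TRUE)
  dev <- compute_deviations(est$mc, est$tot, est$eligible,
                            assign_windows(scen$truth$sites), type)
  frac <- sum(dev$mc_sum) / sum(dev$total_sum)
  value <- 100 * if (type == "loss") 1 - frac else frac
  list(value = value, truth = if (type == "loss") 7.3 else 0.09,
       n = n_f2 * n_sites)
}

#' Recover transgenerational epimutation rates
#'
#' Simulates a grandparent-to-F1 pedigree in which every site starts
#' methylated (loss frame) or unmethylated (gain frame) with the planted
#' per-generation flip rate (0.2% losses, 0.04% gains), infers the
#' grand-parental state from pooled parental replicates and the F1 allele
#' states from F2 segregation, applies the stability filters, and estimates
#' the per-generation rate (averaged over the N and S lineages) in percent.
#'
#' @param type `"loss"` or `"gain"`.
#' @param seed Integer seed.
#' @param n_sites Sites simulated.
#' @param n_f2 F2 individuals used for F1 inference.
#' @param coverage Mean read depth.
#' @return List: `value` (% per generation per site), `truth`, `n`.
#' @export
recovery_epimutation <- function(type = c("loss", "gain"), seed = 1L,
                                 n_sites = 100000L, n_f2 = 100L,
                                 coverage = 10) {
  type <- match.arg(type)
  cfg <- neutral_config(
    n_sites = n_sites, n_f2 = n_f2, coverage_mean = coverage,
    frac_methylated_any_parent = if (type == "loss") 1 else 0,
    frac_differential = 0,
    marker_spacing_bp = 60000L, marker_coverage_mean = 1,
    seed = seed)
  # override the neutral_config zeros: the epimutation process is the one
  # under study here
  cfg$epimutation_loss_rate <- 0.002
  cfg$epimutation_gain_rate <- 0.0004
  scen <- simulate_scenario(cfg)
  rd <- scen$reads
  anc <- infer_ancestry_all(rd$marker_n, rd$marker_s, scen$truth$map)
  sa <- ancestry_at_sites(anc$map_state, scen$truth$map, scen$truth$sites)
  f1 <- infer_f1_epigenotype(rd$mc, rd$tot, sa)
  par_n <- infer_parental_state(rd$parent_mc$N, rd$parent_tot$N)
  par_s <- infer_parental_state(rd$parent_mc$S, rd$parent_tot$S)
  # per-site mean somatic deviations for the stability filter
  eg <- eligible_sites(f1, sa, "gain")
  el <- eligible_sites(f1, sa, "loss")
  mcf <- matrix(nonconversion_filter(rd$mc, rd$tot), nrow(rd$mc))
  tg <- rowSums(rd$tot * eg); tl <- rowSums(rd$tot * el)
  gain_mean <- ifelse(tg > 0, rowSums(mcf * eg) / tg, NA_real_)
  loss_mean <- ifelse(tl > 0, 1 - rowSums(rd$mc * el) / tl, NA_real_)
  rates <- numeric(0)
  for (line in c("N", "S")) {
    gp <- if (line == "N") par_n$state else par_s$state
    f1s <- if (line == "N") f1$n_state else f1$s_state
    flt <- filter_stable_sites(gain_mean, loss_mean, gp, f1s)
    e <- estimate_rates(gp, f1s, flt$retained, lineage = line)
    rates <- c(rates, if (type == "loss") e$loss_rate else e$gain_rate)
  }
  list(value = 100 * mean(rates, na.rm = TRUE),
       truth = if (type == "loss") 0.2 else 0.04,
       n = n_sites)
}

#' Recover a stratified deviation effect
#'
#' Each frame plants one modifier of the somatic deviation process with the
#' published effect size, simulates, estimates deviations with the standard
#' path (F1 epigenotype inferred from the F2 data; true local ancestry is
#' used so the frame isolates the stratified estimator), and recovers the
#' effect with [stratified_summary()] / [stratum_ratio()].
#'
#' Frames: `"peri_gain"` (pericentromere/arm gain fold 2.8), `"cgt_loss"`
#' (CGT loss excess 22%), `"nn_gain"` (NN vs SS gain excess 29%),
#' `"ss_loss"` (SS vs NN loss excess 2%), `"diff_gain"` / `"diff_loss"`
#' (differential-site folds 10 and 2).
#'
#' @param frame Frame name (above).
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the CI.
#' @return List: `value` (ratio or percent excess, matching the published
#'   scale), `truth`, `ci`, `n` (eligible site-individual observations).
#' @export
recovery_fold <- function(frame = c("peri_gain", "cgt_loss", "nn_gain",
                                    "ss_loss", "diff_gain", "diff_loss"),
                          seed = 1L, n_boot = 1000L) {
  frame <- match.arg(frame)
  fr <- switch(frame,
    peri_gain = list(type = "gain", n_sites = 40000L, n_f2 = 200L,
                     coverage = 5, frac_meth = 0,
                     over = list(gain_fold_pericentromere = 2.8,
                                 nonconversion_rate = 0)),
    cgt_loss = list(type = "loss", n_sites = 40000L, n_f2 = 200L,
                    coverage = 5, frac_meth = 1,
                    over = list(loss_fold_cgt = 1.22)),
    nn_gain = list(type = "gain", n_sites = 40000L, n_f2 = 308L,
                   coverage = 5, frac_meth = 0,
                   over = list(gain_fold_nn_vs_ss = 1.29,
                               nonconversion_rate = 0)),
    ss_loss = list(type = "loss", n_sites = 1000L, n_f2 = 200L,
                   coverage = 20, frac_meth = 1,
                   over = list(loss_fold_ss_vs_nn = 1.02)),
    diff_gain = list(type = "gain", n_sites = 50000L, n_f2 = 200L,
                     coverage = 5, frac_meth = 0.25,
                     over = list(gain_fold_differential = 10,
                                 nonconversion_rate = 0)),
    diff_loss = list(type = "loss", n_sites = 50000L, n_f2 = 200L,
                     coverage = 5, frac_meth = 0.25,
                     over = list(loss_fold_differential = 2)))
  args <- c(list(n_sites = fr$n_sites, n_f2 = fr$n_f2,
                 coverage_mean = fr$coverage,
                 frac_methylated_any_parent = fr$frac_meth,
                 frac_differential = if (fr$frac_meth %in% c(0, 1)) 0
                 else 0.45,
                 marker_spacing_bp = 60000L, seed = seed),
            fr$over)
  cfg <- do.call(neutral_config, args)
  scen <- simulate_scenario(cfg)
  est <- recovery_estimate(scen, fr$type, use_hmm = FALSE)
  st <- scen$truth$sites
  strata <- switch(frame,
    peri_gain = ifelse(st$pericentromere, "peri", "arm"),
    cgt_loss = st$context,
    nn_gain = ,
    ss_loss = matrix(c("SS", "NS", "NN")[scen$truth$site_n_alleles + 1L],
                     nrow(st)),
    diff_gain = ,
    diff_loss = ifelse(st$diff, "diff", "same"))
  ss <- stratified_summary(est$mc, est$tot, est$eligible, strata,
                           fr$type, n_boot = n_boot,
                           seed = seed + 1000L)
  res <- switch(frame,
    peri_gain = stratum_ratio(ss, "peri", "arm"),
    cgt_loss = stratum_ratio(ss, "CGT", c("CGA", "CGC", "CGG")),
    nn_gain = stratum_ratio(ss, "NN", "SS"),
    ss_loss = stratum_ratio(ss, "SS", "NN"),
    diff_gain = ,
    diff_loss = stratum_ratio(ss, "diff", "same"))
  as_ratio <- frame %in% c("peri_gain", "diff_gain", "diff_loss")
  truth <- switch(frame, peri_gain = 2.8, cgt_loss = 22, nn_gain = 29,
                  ss_loss = 2, diff_gain = 10, diff_loss = 2)
  list(value = if (as_ratio) res$ratio else res$excess_pct,
       truth = truth,
       ci = if (as_ratio) res$ci else res$excess_ci,
       n = sum(est$eligible & est$tot > 0))
}

#' Recover the variance explained by a planted QTL
#'
#' Simulates window-deviation phenotypes for F2 individuals with one
#' additive biallelic QTL of known variance explained, runs the Haley-Knott
#' scan to localise it, partitions the variance at the peak marker, and
#' averages the recovered QTL component over replicates.
#'
#' @param seed Integer seed.
#' @param ve Planted variance explained (fraction).
#' @param n_f2 F2 individuals per replicate.
#' @param n_reps Replicates averaged.
#' @return List: `value` (QTL share, % of phenotypic variance), `truth`,
#'   `n` (`n_reps`), `localisation_cm` (per-replicate |peak - true| in cM),
#'   `shares` (per-replicate QTL shares).
#' @export
recovery_qtl_ve <- function(seed = 1L, ve = 0.05, n_f2 = 308L,
                            n_reps = 50L) {
  set.seed(as.integer(seed))
  cfg <- neutral_config(n_sites = 10L, n_f2 = n_f2,
                        marker_spacing_bp = 500000L,
                        marker_coverage_mean = 0)
  parents <- simulate_parents(cfg)
  map <- marker_grid(cfg)
  true_m <- which(map$chrom == "chr3")[
    which.min(abs(map$bp[map$chrom == "chr3"] - cfg$chrom_length_bp / 2))]
  temp <- factor(rep_len(cfg$temperatures, n_f2))
  shares <- numeric(n_reps)
  loc_cm <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    truth <- simulate_f2(cfg, parents)
    k <- truth$marker_n_alleles          # markers x individuals
    y <- simulate_phenotype_qtl(k[true_m, ] - 1, ve)
    a <- t(k - 1)
    d <- t((k == 1L) + 0)
    sc <- scan_window(y, a, d, temp)
    peak <- sc$marker[which.max(sc$lod_additive)]
    loc_cm[r] <- abs(map$cM[peak] - map$cM[true_m]) +
      ifelse(map$chrom[peak] == map$chrom[true_m], 0, 1000)
    # the QTL component is reported at the true locus; the scan peak only
    # enters the localisation summary
    vp <- variance_partition(y, temperature = temp,
                             qtl = list(QTL1 = factor(k[true_m, ])))
    shares[r] <- vp$shares[["QTL1"]]
  }
  list(value = 100 * mean(shares), truth = 100 * ve, n = n_reps,
       localisation_cm = loc_cm, shares = shares)
}
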