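#' Simulation configuration for the F2 methylome study design
#'
#' Builds a validated configuration for the forward simulator. Defaults
#' describe the study design the pipeline targets: two divergent inbred
#' parental lines ("northern" N and "southern" S), an F2 intercross grown at
#' two temperatures, ~650k exonic CG sites with binary parental methylation
#' states, somatic gain/loss processes with regional, context, ancestry and
#' differential-site modifiers, transgenerational epimutation, and shallow
#' bisulfite read sampling.
#'
#' Key default choices:
#' * 25% of sites methylated in at least one parent; 45% of those differ
#'   between the parents; 70% of differing sites are methylated only in N.
#' * Somatic base rates: loss 7.3% and gain 0.09% per read.
#' * Modifier folds: pericentromeric gains x2.8, CGT losses x1.22, N-allele
#'   gains x1.29, S-allele losses x1.02, differential-site gains x10 and
#'   losses x2.
#' * Transgenerational epimutation: gains 0.04%/generation, losses
#'   0.2%/generation.
#' * Bisulfite non-conversion 0.3%; over-conversion 0 (no usable estimate).
#' * Chromosomes of 1 Morgan each, crossovers Poisson without interference
#'   (Haldane).
#'
#' @param n_sites Number of CG sites genome-wide.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical length per chromosome (bp).
#' @param pericentromere_fraction Central fraction of each chromosome flagged
#'   pericentromeric.
#' @param frac_methylated_any_parent Fraction of sites methylated in >= 1
#'   parental line.
#' @param frac_differential Of those, fraction differing between the lines.
#' @param frac_north_only_of_differential Of differing sites, fraction
#'   methylated only in the northern line.
#' @param n_f2 Number of F2 individuals.
#' @param n_parent_replicates Sequenced replicate individuals per parental
#'   line.
#' @param temperatures Growth-temperature labels.
#' @param marker_spacing_bp Spacing of the SNP marker grid.
#' @param coverage_mean Mean per-site read depth (Poisson).
#' @param marker_coverage_mean Mean per-marker read depth (Poisson).
#' @param genotyping_error Probability a marker read reports the wrong
#'   parental allele.
#' @param nonconversion_rate Bisulfite non-conversion rate.
#' @param overconversion_rate Bisulfite over-conversion rate.
#' @param gain_rate_base,loss_rate_base Somatic per-read gain/loss base
#'   probabilities.
#' @param gain_fold_pericentromere Gain multiplier in pericentromeres.
#' @param loss_fold_cgt Loss multiplier at CGT-context sites.
#' @param gain_fold_nn_vs_ss Gain multiplier for N-origin alleles.
#' @param loss_fold_ss_vs_nn Loss multiplier for S-origin alleles.
#' @param gain_fold_differential,loss_fold_differential Multipliers at sites
#'   whose parental states differ.
#' @param gain_fold_cold,loss_fold_cold Multipliers applied at the first
#'   (cold) temperature label.
#' @param epimutation_gain_rate,epimutation_loss_rate Transgenerational
#'   state-flip rates per site per generation.
#' @param morgans_per_chromosome Genetic length of each chromosome.
#' @param qtl_specs List of trans-acting QTL, each a list with fields
#'   `chrom`, `pos`, `target` ("gain" or "loss"), `variance_explained`,
#'   optional `dominance` (logical; TRUE makes the high-rate allele
#'   recessive) and `temperature_restriction` (a temperature label).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 650000L,
                       n_chromosomes = 5L,
                       chrom_length_bp = 24000000L,
                       pericentromere_fraction = 0.2,
                       frac_methylated_any_parent = 0.25,
                       frac_differential = 0.45,
                       frac_north_only_of_differential = 0.70,
                       n_f2 = 308L,
                       n_parent_replicates = 4L,
                       temperatures = c("4C", "16C"),
                       marker_spacing_bp = 30000L,
                       coverage_mean = 5,
                       marker_coverage_mean = 1,
                       genotyping_error = 0.01,
                       nonconversion_rate = 0.003,
                       overconversion_rate = 0,
                       gain_rate_base = 0.0009,
                       loss_rate_base = 0.073,
                       gain_fold_pericentromere = 2.8,
                       loss_fold_cgt = 1.22,
                       gain_fold_nn_vs_ss = 1.29,
                       loss_fold_ss_vs_nn = 1.02,
                       gain_fold_differential = 10,
                       loss_fold_differential = 2,
                       gain_fold_cold = 1,
                       loss_fold_cold = 1,
                       epimutation_gain_rate = 0.0004,
                       epimutation_loss_rate = 0.002,
                       morgans_per_chromosome = 1,
                       qtl_specs = list(),
                       seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("pericentromere_fraction", "frac_methylated_any_parent",
                   "frac_differential", "frac_north_only_of_differential",
                   "nonconversion_rate", "overconversion_rate",
                   "gain_rate_base", "loss_rate_base",
                   "epimutation_gain_rate", "epimutation_loss_rate",
                   "genotyping_error")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: field '", f, "' must be a fraction in [0, 1]")
    }
  }
  fold_fields <- grep("_fold_", names(cfg), value = TRUE)
  for (f in fold_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("sim_config: field '", f, "' must be a positive fold factor")
    }
  }
  pos_fields <- c("n_sites", "n_chromosomes", "chrom_length_bp", "n_f2",
                  "n_parent_replicates", "marker_spacing_bp",
                  "morgans_per_chromosome")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("sim_config: field '", f, "' must be positive")
    }
  }
  if (cfg$coverage_mean < 0) stop("sim_config: field 'coverage_mean' must be >= 0")
  if (length(cfg$temperatures) < 1) stop("sim_config: field 'temperatures' is empty")
  for (q in cfg$qtl_specs) {
    need <- c("chrom", "pos", "target", "variance_explained")
    if (!all(need %in% names(q))) {
      stop("sim_config: qtl_specs entries need fields ",
           paste(need, collapse = ", "))
    }
    if (!q$target %in% c("gain", "loss")) {
      stop("sim_config: qtl target must be 'gain' or 'loss'")
    }
    ve <- q$variance_explained
    if (!is.numeric(ve) || ve < 0 || ve >= 1) {
      stop("sim_config: field 'variance_explained' must be in [0, 1)")
    }
  }
  invisible(cfg)
}

#' Simulate parental methylomes
#'
#' Assigns each CG site a chromosome, position, 3-mer context (uniform over
#' CGA/CGT/CGC/CGG), a pericentromere flag, and binary methylation states for
#' the northern and southern parental lines matching the configured site
#' fractions in expectation.
#'
#' @param cfg A [sim_config()].
#' @return A `data.table`: chrom, pos, context, pericentromere, n_state,
#'   s_state, diff, meth_any.
#' @export
simulate_parents <- function(cfg) {
  validate_sim_config(cfg)
  n <- as.integer(cfg$n_sites)
  nchr <- as.integer(cfg$n_chromosomes)
  L <- as.integer(cfg$chrom_length_bp)
  per_chr <- diff(round(seq(0, n, length.out = nchr + 1)))
  chrom <- rep(paste0("chr", seq_len(nchr)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) sort(sample.int(L, k))),
                use.names = FALSE)
  context <- sample(CG_CONTEXTS, n, replace = TRUE)
  mid <- L / 2
  half <- L * cfg$pericentromere_fraction / 2
  peri <- abs(pos - mid) < half

  meth_any <- runif(n) < cfg$frac_methylated_any_parent
  diff <- meth_any & (runif(n) < cfg$frac_differential)
  north_only <- diff & (runif(n) < cfg$frac_north_only_of_differential)
  n_state <- integer(n)
  s_state <- integer(n)
  n_state[meth_any & !diff] <- 1L
  s_state[meth_any & !diff] <- 1L
  n_state[north_only] <- 1L
  s_state[diff & !north_only] <- 1L

  data.table::data.table(chrom = chrom, pos = pos, context = context,
                         pericentromere = peri,
                         n_state = n_state, s_state = s_state,
                         diff = n_state != s_state,
                         meth_any = (n_state + s_state) > 0L)
}

# Marker grid covering each chromosome end to end; cM from the configured
# genetic length (uniform recombination along bp).
marker_grid <- function(cfg) {
  L <- cfg$chrom_length_bp
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    bp <- unique(c(seq(1L, L, by = as.integer(cfg$marker_spacing_bp)), L))
    data.table::data.table(chrom = paste0("chr", ci), bp = as.integer(bp),
                           cM = bp / L * cfg$morgans_per_chromosome * 100)
  })
  map <- data.table::rbindlist(maps)
  map[, marker := sprintf("m_%s_%d", chrom, bp)]
  data.table::setcolorder(map, c("marker", "chrom", "bp", "cM"))
  map[]
}

# One meiotic gamete per chromosome: crossover count ~ Poisson(Morgans),
# positions uniform, no interference (Haldane). Returns the list of
# crossover positions and the starting parental origin (1 = N).
draw_gamete <- function(cfg) {
  lapply(seq_len(cfg$n_chromosomes), function(ci) {
    k <- rpois(1L, cfg$morgans_per_chromosome)
    list(xo = sort(runif(k, 1, cfg$chrom_length_bp)),
         start = sample(0:1, 1L))
  })
}

# Parental origin (1 = N allele) of a gamete at given positions.
gamete_origin_at <- function(gamete_chr, pos) {
  par <- findInterval(pos, gamete_chr$xo) %% 2L
  as.integer((gamete_chr$start + par) %% 2L)
}

#' Simulate the F1/F2 pedigree
#'
#' Applies two generations of transgenerational epimutation to the parental
#' epialleles to obtain the F1 epialleles, then draws two recombinant gametes
#' per F2 individual (crossovers as a Poisson process per chromosome, Haldane
#' model) and records local ancestry (number of N-origin alleles, 0/1/2) at
#' every CG site and every marker.
#'
#' @param cfg A [sim_config()].
#' @param parents Output of [simulate_parents()].
#' @return A list of class `epi_truth`: `sites`, `f1_n_allele`,
#'   `f1_s_allele`, `site_n_alleles` (sites x individuals), `map`,
#'   `marker_n_alleles` (markers x individuals), `crossovers`.
#' @export
simulate_f2 <- function(cfg, parents) {
  n_sites <- nrow(parents)
  n_f2 <- as.integer(cfg$n_f2)

  # grandparent -> parent -> F1: two independent chances to flip per allele
  flip2 <- function(state) {
    s <- state
    for (gen in 1:2) {
      p <- ifelse(s == 1L, cfg$epimutation_loss_rate, cfg$epimutation_gain_rate)
      s <- ifelse(runif(length(s)) < p, 1L - s, s)
    }
    as.integer(s)
  }
  f1_n <- flip2(parents$n_state)
  f1_s <- flip2(parents$s_state)

  map <- marker_grid(cfg)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  site_idx <- split(seq_len(n_sites), factor(parents$chrom, levels = chroms))
  marker_idx <- split(seq_len(nrow(map)), factor(map$chrom, levels = chroms))

  site_anc <- matrix(0L, n_sites, n_f2)
  marker_anc <- matrix(0L, nrow(map), n_f2)
  crossovers <- vector("list", n_f2)
  for (j in seq_len(n_f2)) {
    g1 <- draw_gamete(cfg)
    g2 <- draw_gamete(cfg)
    crossovers[[j]] <- list(gamete1 = lapply(g1, `[[`, "xo"),
                            gamete2 = lapply(g2, `[[`, "xo"))
    for (ci in seq_along(chroms)) {
      si <- site_idx[[ci]]
      mi <- marker_idx[[ci]]
      o1s <- gamete_origin_at(g1[[ci]], parents$pos[si])
      o2s <- gamete_origin_at(g2[[ci]], parents$pos[si])
      site_anc[si, j] <- o1s + o2s
      o1m <- gamete_origin_at(g1[[ci]], map$bp[mi])
      o2m <- gamete_origin_at(g2[[ci]], map$bp[mi])
      marker_anc[mi, j] <- o1m + o2m
    }
  }
  structure(list(sites = parents, f1_n_allele = f1_n, f1_s_allele = f1_s,
                 site_n_alleles = site_anc, map = map,
                 marker_n_alleles = marker_anc, crossovers = crossovers),
            class = "epi_truth")
}

# Analytic calibration of the QTL genotype multiplier.
#
# A trans QTL multiplies the per-read deviation rate by (1 + delta * u_j)
# where u_j is a centred genotype coding for individual j (additive:
# u = k - 1 for k N alleles, Var(u) = 1/2; recessive: u = 1{k == 2} - 1/4,
# Var(u) = 3/16). The 500-kb window phenotype is a read-weighted mean over
# ~R reads, so its variance decomposes as
#   Var(y) ~= rate^2 delta^2 Var(u) + rate (1 - rate) / R .
# Setting the genetic share to the requested variance_explained v and
# solving gives
#   delta = sqrt( v / (1 - v) * (1 - rate) / (rate * R * Var(u)) ).
qtl_delta <- function(variance_explained, rate, reads_per_window, u_var) {
  v <- variance_explained
  if (v <= 0) return(0)
  sqrt(v / (1 - v) * (1 - rate) / (rate * reads_per_window * u_var))
}

# Centred genotype coding for a QTL spec given allele counts k in {0,1,2}.
qtl_coding <- function(k, dominance = FALSE) {
  if (isTRUE(dominance)) ifelse(k == 2L, 1, 0) - 0.25 else k - 1
}

# Per-individual rate multipliers implied by the configured QTL.
qtl_multipliers <- function(cfg, truth, temperature) {
  n_f2 <- ncol(truth$site_n_alleles)
  mult <- list(gain = rep(1, n_f2), loss = rep(1, n_f2))
  if (!length(cfg$qtl_specs)) return(mult)
  window_bp <- 500000
  sites_per_window <- nrow(truth$sites) /
    (cfg$n_chromosomes * cfg$chrom_length_bp / window_bp)
  for (q in cfg$qtl_specs) {
    mi <- which(truth$map$chrom == q$chrom)
    if (!length(mi)) stop("qtl spec chrom not in map: ", q$chrom)
    mi <- mi[which.min(abs(truth$map$bp[mi] - q$pos))]
    k <- truth$marker_n_alleles[mi, ]
    dom <- isTRUE(q$dominance)
    u <- qtl_coding(k, dom)
    rate <- if (q$target == "gain") cfg$gain_rate_base else cfg$loss_rate_base
    # fraction of sites eligible for this deviation type (both alleles in
    # the susceptible state), used to scale reads per window
    elig <- if (q$target == "gain") {
      mean(truth$f1_n_allele == 0L & truth$f1_s_allele == 0L)
    } else {
      mean(truth$f1_n_allele == 1L & truth$f1_s_allele == 1L)
    }
    R <- max(1, sites_per_window * elig * cfg$coverage_mean)
    u_var <- if (dom) 3 / 16 else 0.5
    delta <- qtl_delta(q$variance_explained, rate, R, u_var)
    m <- pmax(0, 1 + delta * u)
    if (!is.null(q$temperature_restriction)) {
      m[temperature != q$temperature_restriction] <- 1
    }
    mult[[q$target]] <- mult[[q$target]] * m
  }
  mult
}

# Probability that a sequenced read reports "methylated" for one allele.
# allele_state 1: methylated unless somatically lost (prob l) or
# over-converted; a lost/unmethylated template still reads methylated at the
# non-conversion rate.
read_meth_prob <- function(allele_state, gain, loss, nc, oc) {
  ifelse(allele_state == 1L,
         (1 - loss) * (1 - oc) + loss * nc,
         gain * (1 - oc) + (1 - gain) * nc)
}

#' Simulate bisulfite reads and marker allele counts
#'
#' Per site and individual, read depth is Poisson(`coverage_mean`) and each
#' read derives from one of the two inherited epialleles, flipped by the
#' somatic gain/loss probability after all modifiers (context,
#' pericentromere, allele ancestry, differential status, temperature, QTL),
#' then corrupted by bisulfite non-/over-conversion. Marker allele counts are
#' drawn from true ancestry with the configured genotyping error. Parental
#' replicate methylomes are sampled with the same read model (no QTL, pure
#' line ancestry).
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_f2()].
#' @param temperature Character vector assigning each F2 individual a label
#'   from `cfg$temperatures`; default alternates labels.
#' @return List of class `epi_reads`: `mc`, `tot` (sites x F2 individuals),
#'   `marker_n`, `marker_s` (markers x individuals), `parent_mc`,
#'   `parent_tot` (lists with matrices for lines N and S), `temperature`.
#' @export
simulate_reads <- function(cfg, truth, temperature = NULL) {
  n_sites <- nrow(truth$sites)
  n_f2 <- ncol(truth$site_n_alleles)
  if (is.null(temperature)) {
    temperature <- rep_len(cfg$temperatures, n_f2)
  }
  if (!all(temperature %in% cfg$temperatures)) {
    stop("temperature labels not in cfg$temperatures: ",
         paste(setdiff(temperature, cfg$temperatures), collapse = ", "))
  }

  st <- truth$sites
  gain_site <- cfg$gain_rate_base *
    ifelse(st$pericentromere, cfg$gain_fold_pericentromere, 1) *
    ifelse(st$diff, cfg$gain_fold_differential, 1)
  loss_site <- cfg$loss_rate_base *
    ifelse(st$context == "CGT", cfg$loss_fold_cgt, 1) *
    ifelse(st$diff, cfg$loss_fold_differential, 1)

  qmult <- qtl_multipliers(cfg, truth, temperature)
  cold <- cfg$temperatures[1]

  nc <- cfg$nonconversion_rate
  oc <- cfg$overconversion_rate

  mc <- matrix(0L, n_sites, n_f2)
  tot <- matrix(0L, n_sites, n_f2)
  for (j in seq_len(n_f2)) {
    k <- truth$site_n_alleles[, j]
    a1 <- ifelse(k >= 1L, truth$f1_n_allele, truth$f1_s_allele)
    a2 <- ifelse(k == 2L, truth$f1_n_allele, truth$f1_s_allele)
    tmult_g <- if (temperature[j] == cold) cfg$gain_fold_cold else 1
    tmult_l <- if (temperature[j] == cold) cfg$loss_fold_cold else 1
    g1 <- pmin(1, gain_site * ifelse(k >= 1L, cfg$gain_fold_nn_vs_ss, 1) *
                 qmult$gain[j] * tmult_g)
    g2 <- pmin(1, gain_site * ifelse(k == 2L, cfg$gain_fold_nn_vs_ss, 1) *
                 qmult$gain[j] * tmult_g)
    l1 <- pmin(1, loss_site * ifelse(k >= 1L, 1, cfg$loss_fold_ss_vs_nn) *
                 qmult$loss[j] * tmult_l)
    l2 <- pmin(1, loss_site * ifelse(k == 2L, 1, cfg$loss_fold_ss_vs_nn) *
                 qmult$loss[j] * tmult_l)
    p_cell <- 0.5 * (read_meth_prob(a1, g1, l1, nc, oc) +
                       read_meth_prob(a2, g2, l2, nc, oc))
    depth <- rpois(n_sites, cfg$coverage_mean)
    tot[, j] <- depth
    mc[, j] <- rbinom(n_sites, depth, p_cell)
  }

  # parental replicates: pure-line diplotypes with the same somatic model
  parent_mc <- list(); parent_tot <- list()
  for (line in c("N", "S")) {
    state <- if (line == "N") st$n_state else st$s_state
    g <- pmin(1, gain_site * if (line == "N") cfg$gain_fold_nn_vs_ss else 1)
    l <- pmin(1, loss_site * if (line == "N") 1 else cfg$loss_fold_ss_vs_nn)
    p <- read_meth_prob(state, g, l, nc, oc)
    pm <- matrix(0L, n_sites, cfg$n_parent_replicates)
    pt <- matrix(0L, n_sites, cfg$n_parent_replicates)
    for (r in seq_len(cfg$n_parent_replicates)) {
      depth <- rpois(n_sites, cfg$coverage_mean)
      pt[, r] <- depth
      pm[, r] <- rbinom(n_sites, depth, p)
    }
    parent_mc[[line]] <- pm
    parent_tot[[line]] <- pt
  }

  # marker allele counts from true ancestry
  n_mark <- nrow(truth$map)
  p_n_read <- c(cfg$genotyping_error, 0.5, 1 - cfg$genotyping_error)
  marker_depth <- matrix(rpois(n_mark * n_f2, cfg$marker_coverage_mean),
                         n_mark, n_f2)
  p_read <- matrix(p_n_read[truth$marker_n_alleles + 1L], n_mark, n_f2)
  marker_n <- matrix(rbinom(n_mark * n_f2, marker_depth, p_read),
                     n_mark, n_f2)
  marker_s <- marker_depth - marker_n

  structure(list(mc = mc, tot = tot,
                 marker_n = marker_n, marker_s = marker_s,
                 parent_mc = parent_mc, parent_tot = parent_tot,
                 temperature = temperature),
            class = "epi_reads")
}

#' Simulate a complete scenario
#'
#' Convenience wrapper running [simulate_parents()], [simulate_f2()] and
#' [simulate_reads()] under the configured seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `epi_scenario` with elements `cfg`, `truth`,
#'   `reads`, `meta` (data.table: individual, cross_direction, temperature).
#' @export
simulate_scenario <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  parents <- simulate_parents(cfg)
  truth <- simulate_f2(cfg, parents)
  temperature <- rep_len(cfg$temperatures, cfg$n_f2)
  reads <- simulate_reads(cfg, truth, temperature)
  meta <- data.table::data.table(
    individual = sprintf("F2_%04d", seq_len(cfg$n_f2)),
    cross_direction = "NxS",
    temperature = temperature)
  structure(list(cfg = cfg, truth = truth, reads = reads, meta = meta),
            class = "epi_scenario")
}

#' Write a simulated scenario to disk
#'
#' Emits the file set the pipeline consumes: one allc-style methylome TSV per
#' F2 individual and parental replicate, a long-format marker allele-count
#' TSV, a marker map TSV, BED annotations for pericentromeres and 500-kb
#' windows, a sample metadata TSV, the configuration as YAML, and the
#' simulation truth as JSON (for recovery tests). Files round-trip through
#' the package readers.
#'
#' @param dir Output directory (created if needed).
#' @param scen Output of [simulate_scenario()].
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(dir, scen) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- scen$truth$sites
  write_counts <- function(mc, tot, name) {
    tbl <- data.table::data.table(chrom = st$chrom, pos = st$pos,
                                  strand = "+", context = st$context,
                                  mc_count = mc, total_count = tot,
                                  methylated_flag = as.integer(mc > 0L))
    write_methylome(tbl, file.path(dir, paste0(name, ".allc.tsv")))
  }
  for (j in seq_len(nrow(scen$meta))) {
    write_counts(scen$reads$mc[, j], scen$reads$tot[, j],
                 scen$meta$individual[j])
  }
  for (line in c("N", "S")) {
    for (r in seq_len(ncol(scen$reads$parent_mc[[line]]))) {
      write_counts(scen$reads$parent_mc[[line]][, r],
                   scen$reads$parent_tot[[line]][, r],
                   sprintf("parent_%s_rep%d", line, r))
    }
  }
  map <- scen$truth$map
  data.table::fwrite(map, file.path(dir, "map.tsv"), sep = "\t")
  marker_long <- data.table::data.table(
    individual = rep(scen$meta$individual, each = nrow(map)),
    marker = rep(map$marker, nrow(scen$meta)),
    n_reads = as.vector(scen$reads$marker_n),
    s_reads = as.vector(scen$reads$marker_s))
  data.table::fwrite(marker_long, file.path(dir, "markers.tsv"), sep = "\t")
  data.table::fwrite(scen$meta, file.path(dir, "metadata.tsv"), sep = "\t")

  L <- scen$cfg$chrom_length_bp
  chroms <- paste0("chr", seq_len(scen$cfg$n_chromosomes))
  peri <- data.table::data.table(
    chrom = chroms,
    start = as.integer(L / 2 - L * scen$cfg$pericentromere_fraction / 2),
    end = as.integer(L / 2 + L * scen$cfg$pericentromere_fraction / 2))
  data.table::fwrite(peri, file.path(dir, "pericentromere.bed"), sep = "\t",
                     col.names = FALSE)
  win <- tile_windows(chroms, L, 500000L)
  data.table::fwrite(win[, .(chrom, start, end)],
                     file.path(dir, "windows.bed"), sep = "\t",
                     col.names = FALSE)
  cfg_out <- scen$cfg
  class(cfg_out) <- NULL
  cfg_out$qtl_specs <- NULL
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))

  xo_flat <- data.table::rbindlist(lapply(
    seq_along(scen$truth$crossovers), function(j) {
      ind <- scen$truth$crossovers[[j]]
      data.table::rbindlist(lapply(c("gamete1", "gamete2"), function(g) {
        data.table::rbindlist(lapply(seq_along(ind[[g]]), function(ci) {
          if (!length(ind[[g]][[ci]])) return(NULL)
          data.table::data.table(individual = j, gamete = g,
                                 chrom_index = ci, pos = ind[[g]][[ci]])
        }))
      }))
    }))
  truth_json <- list(
    sites = as.list(scen$truth$sites),
    f1_n_allele = scen$truth$f1_n_allele,
    f1_s_allele = scen$truth$f1_s_allele,
    site_n_alleles = scen$truth$site_n_alleles,
    map = as.list(map),
    marker_n_alleles = scen$truth$marker_n_alleles,
    n_individuals = length(scen$truth$crossovers),
    n_chromosomes = scen$cfg$n_chromosomes,
    crossovers = xo_flat)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Reload simulation truth written by [write_scenario()]
#'
#' @param dir Scenario directory.
#' @return An `epi_truth` list equal to the one written.
#' @export
read_truth <- function(dir) {
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  sites <- data.table::as.data.table(tj$sites)
  xo_flat <- data.table::as.data.table(tj$crossovers)
  nchr <- tj$n_chromosomes
  xo <- lapply(seq_len(tj$n_individuals), function(j) {
    lapply(setNames(nm = c("gamete1", "gamete2")), function(g) {
      lapply(seq_len(nchr), function(ci) {
        if (!nrow(xo_flat)) return(numeric(0))
        sort(xo_flat[individual == j & gamete == g &
                       chrom_index == ci]$pos)
      })
    })
  })
  structure(list(sites = sites,
                 f1_n_allele = as.integer(tj$f1_n_allele),
                 f1_s_allele = as.integer(tj$f1_s_allele),
                 site_n_alleles = matrix(as.integer(tj$site_n_alleles),
                                         nrow = nrow(sites)),
                 map = data.table::as.data.table(tj$map),
                 marker_n_alleles = matrix(as.integer(tj$marker_n_alleles),
                                           nrow = length(tj$map$marker)),
                 crossovers = xo),
            class = "epi_truth")
}

# Non-overlapping genomic windows tiled from position 1 (0-based half-open,
# BED convention); the final partial window is kept.
tile_windows <- function(chroms, chrom_length, window_bp) {
  out <- lapply(seq_along(chroms), function(ci) {
    start <- seq(0L, chrom_length - 1L, by = as.integer(window_bp))
    data.table::data.table(chrom = chroms[ci], start = start,
                           end = pmin(start + as.integer(window_bp),
                                      as.integer(chrom_length)))
  })
  win <- data.table::rbindlist(out)
  win[, window := sprintf("%s:%d-%d", chrom, start, end)]
  win[]
}
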