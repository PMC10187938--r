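test_that("sim_config validation names the offending field", {
  expect_error(sim_config(frac_differential = 1.2), "frac_differential")
  expect_error(sim_config(nonconversion_rate = -0.1), "nonconversion_rate")
  expect_error(sim_config(gain_fold_pericentromere = 0),
               "gain_fold_pericentromere")
  expect_error(sim_config(n_f2 = 0), "n_f2")
  expect_error(sim_config(qtl_specs = list(list(chrom = "chr1"))), "qtl")
  expect_s3_class(sim_config(n_sites = 10), "sim_config")
})

test_that("parental state fractions match configuration in expectation", {
  set.seed(31)
  n <- 100000L
  cfg <- tiny_cfg(n_sites = n)
  par <- simulate_parents(cfg)
  expect_equal(nrow(par), n)
  expect_true(all(diff(par[chrom == "chr1"]$pos) > 0))
  p1 <- mean(par$meth_any)
  expect_lt(abs(p1 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  p2 <- mean(par[meth_any == TRUE]$diff)
  expect_lt(abs(p2 - 0.45), 3 * sqrt(0.45 * 0.55 / sum(par$meth_any)))
  p3 <- mean(par[diff == TRUE, n_state == 1L])
  expect_lt(abs(p3 - 0.70), 3 * sqrt(0.7 * 0.3 / sum(par$diff)))
})

test_that("degenerate parental fractions behave as stated", {
  set.seed(32)
  par0 <- simulate_parents(tiny_cfg(n_sites = 500,
                                    frac_methylated_any_parent = 0))
  expect_true(all(par0$n_state == 0L & par0$s_state == 0L))
  par_same <- simulate_parents(tiny_cfg(n_sites = 500,
                                        frac_differential = 0))
  expect_equal(par_same$n_state, par_same$s_state)
})

test_that("F2 ancestry is Mendelian and crossovers are Poisson", {
  set.seed(33)
  cfg <- tiny_cfg(n_sites = 50, n_f2 = 1500L)
  par <- simulate_parents(cfg)
  truth <- simulate_f2(cfg, par)
  # marginal at an arbitrary marker: (0.25, 0.5, 0.25) within 4 SE
  m <- 7L
  k <- truth$marker_n_alleles[m, ]
  for (g in 0:2) {
    p <- c(0.25, 0.5, 0.25)[g + 1]
    se <- sqrt(p * (1 - p) / cfg$n_f2)
    expect_lt(abs(mean(k == g) - p), 4 * se)
  }
  # expected crossovers per chromosome = Morgans x 2 gametes
  n_xo <- vapply(truth$crossovers, function(ind) {
    length(unlist(ind$gamete1)) + length(unlist(ind$gamete2))
  }, numeric(1))
  lam <- cfg$morgans_per_chromosome * 2 * cfg$n_chromosomes
  expect_lt(abs(mean(n_xo) - lam), 4 * sqrt(lam / cfg$n_f2))
  # ancestry changes only at crossover positions: uniform between them
  ind <- 1L
  xo1 <- truth$crossovers[[ind]]$gamete1[[1]]
  xo2 <- truth$crossovers[[ind]]$gamete2[[1]]
  brk <- sort(c(xo1, xo2))
  sites1 <- which(truth$sites$chrom == "chr1")
  seg <- findInterval(truth$sites$pos[sites1], brk)
  anc <- truth$site_n_alleles[sites1, ind]
  expect_true(all(tapply(anc, seg, function(v) length(unique(v))) == 1L))
})

test_that("epimutation and recombination zero cases", {
  set.seed(34)
  cfg <- tiny_cfg(n_sites = 300, n_f2 = 10L)
  par <- simulate_parents(cfg)
  truth <- simulate_f2(cfg, par)   # epimutation rates are 0 in tiny_cfg
  expect_equal(truth$f1_n_allele, par$n_state)
  expect_equal(truth$f1_s_allele, par$s_state)

  cfg0 <- tiny_cfg(n_sites = 300, n_f2 = 10L,
                   morgans_per_chromosome = 1e-9)
  truth0 <- simulate_f2(cfg0, simulate_parents(cfg0))
  for (j in 1:10) {
    for (ch in paste0("chr", 1:5)) {
      v <- truth0$site_n_alleles[truth0$sites$chrom == ch, j]
      expect_equal(length(unique(v)), 1L)
    }
  }
})

test_that("f1 epialleles flip at the configured per-generation rates", {
  set.seed(35)
  cfg <- tiny_cfg(n_sites = 200000L, n_f2 = 2L,
                  frac_methylated_any_parent = 1, frac_differential = 0,
                  epimutation_loss_rate = 0.002,
                  epimutation_gain_rate = 0.0004)
  par <- simulate_parents(cfg)
  truth <- simulate_f2(cfg, par)
  # two generations: flip probability 1 - (1 - r)^2
  p2 <- 1 - (1 - 0.002)^2
  flipped <- mean(truth$f1_n_allele != par$n_state)
  expect_lt(abs(flipped - p2), 4 * sqrt(p2 * (1 - p2) / cfg$n_sites))
})

test_that("reads reflect inherited states exactly when all rates are zero", {
  set.seed(36)
  cfg <- tiny_cfg(n_sites = 500, n_f2 = 12L, gain_rate_base = 0,
                  loss_rate_base = 0, nonconversion_rate = 0)
  scen <- simulate_scenario(cfg)
  k <- scen$truth$site_n_alleles
  exp_level <- (k * scen$truth$f1_n_allele +
                  (2L - k) * scen$truth$f1_s_allele) / 2
  with_reads <- scen$reads$tot > 0
  got <- scen$reads$mc[with_reads] / scen$reads$tot[with_reads]
  # homozygous diplotypes must match exactly; heterozygous sites are
  # mixtures and only match in expectation
  hom <- exp_level[with_reads] %in% c(0, 1)
  expect_equal(got[hom], exp_level[with_reads][hom])
})

test_that("zero coverage produces empty counts", {
  set.seed(37)
  cfg <- tiny_cfg(n_sites = 100, n_f2 = 5L, coverage_mean = 0)
  scen <- simulate_scenario(cfg)
  expect_true(all(scen$reads$tot == 0L))
  expect_true(all(scen$reads$mc == 0L))
})

test_that("realized loss frequency matches the base rate with neutral folds", {
  set.seed(38)
  cfg <- tiny_cfg(n_sites = 20000L, n_f2 = 20L,
                  frac_methylated_any_parent = 1, frac_differential = 0,
                  loss_rate_base = 0.073, gain_rate_base = 0,
                  nonconversion_rate = 0)
  scen <- simulate_scenario(cfg)
  unmeth <- sum(scen$reads$tot) - sum(scen$reads$mc)
  n_reads <- sum(scen$reads$tot)
  se <- sqrt(0.073 * 0.927 / n_reads)
  expect_lt(abs(unmeth / n_reads - 0.073), 4 * se)
})

test_that("temperature labels are validated", {
  set.seed(39)
  cfg <- tiny_cfg(n_sites = 50, n_f2 = 4L)
  par <- simulate_parents(cfg)
  truth <- simulate_f2(cfg, par)
  expect_error(simulate_reads(cfg, truth, rep("30C", 4)), "temperature")
})

test_that("scenario files round-trip and are seed-deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- tiny_cfg(n_sites = 300, n_f2 = 6L, seed = 99L)
  scen <- simulate_scenario(cfg)
  write_scenario(dir1, scen)
  write_scenario(dir2, simulate_scenario(cfg))
  for (f in c("F2_0001.allc.tsv", "map.tsv", "markers.tsv", "metadata.tsv",
              "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
  ds <- read_scenario(dir1)
  expect_equal(ds$mc, scen$reads$mc, ignore_attr = TRUE)
  expect_equal(ds$tot, scen$reads$tot, ignore_attr = TRUE)
  expect_equal(ds$marker_n, scen$reads$marker_n, ignore_attr = TRUE)
  expect_equal(ds$sites$pos, scen$truth$sites$pos)

  truth2 <- read_truth(dir1)
  expect_equal(truth2$f1_n_allele, scen$truth$f1_n_allele)
  expect_equal(truth2$site_n_alleles, scen$truth$site_n_alleles,
               ignore_attr = TRUE)
  expect_equal(truth2$map$cM, scen$truth$map$cM)
  expect_equal(truth2$crossovers[[1]]$gamete1,
               scen$truth$crossovers[[1]]$gamete1,
               ignore_attr = TRUE)
})

test_that("writing an empty individual list emits metadata only", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg(n_sites = 50, n_f2 = 2L, seed = 1L)
  scen <- simulate_scenario(cfg)
  scen$meta <- scen$meta[0]
  write_scenario(dir, scen)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_length(list.files(dir, "^F2_.*allc"), 0L)
})
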