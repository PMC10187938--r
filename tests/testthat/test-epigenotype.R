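test_that("grand-parental state from pooled replicates", {
  # replicates (10/10, 8/9): pooled level 18/19 -> methylated
  got <- infer_parental_state(cbind(10L, 8L), cbind(10L, 9L))
  expect_equal(got$level, 18 / 19)
  expect_equal(got$state, "methylated")
  expect_equal(infer_parental_state(cbind(0L, 0L), cbind(10L, 12L))$state,
               "unmethylated")
  expect_equal(infer_parental_state(cbind(5L, 5L), cbind(10L, 10L))$state,
               "ambiguous")
  expect_error(infer_parental_state(cbind(0L), cbind(0L)), "covered")
})

test_that("F1 class follows the allele-state rule table", {
  st <- c("methylated", "unmethylated", "ambiguous", "missing")
  grid <- expand.grid(n = st, s = st, stringsAsFactors = FALSE)
  got <- classify_f1(grid$n, grid$s)
  want <- ifelse(grid$n == "unmethylated" & grid$s == "unmethylated", "00",
          ifelse(grid$n == "methylated" & grid$s == "methylated", "11",
          ifelse(grid$n %in% st[1:2] & grid$s %in% st[1:2], "01",
                 "ambiguous")))
  expect_equal(got, want)
})

test_that("F1 epigenotype inference pools homozygous-ancestry individuals", {
  # 3 sites x 8 individuals; 4 NN, 4 SS
  anc <- matrix(rep(c(2L, 0L), each = 4), 3, 8, byrow = TRUE)
  tot <- matrix(10L, 3, 8)
  mc <- rbind(c(10, 10, 9, 10, 0, 0, 0, 0),    # het: N meth, S unmeth
              c(0, 0, 0, 0, 0, 0, 0, 0),        # 00
              c(10, 10, 10, 10, 10, 9, 10, 10)) # 11
  f1 <- infer_f1_epigenotype(mc, tot, anc, min_individuals = 3L)
  expect_equal(f1$class, c("01", "00", "11"))
  expect_equal(f1$n_state[1], "methylated")
  expect_equal(f1$s_state[1], "unmethylated")
  # too few individuals in a class -> ambiguous, not an error
  f1b <- infer_f1_epigenotype(mc, tot, anc, min_individuals = 5L)
  expect_equal(unique(f1b$class), "ambiguous")
})

test_that("F1 inference is equivariant under N/S label swap", {
  set.seed(51)
  anc <- matrix(sample(c(0L, 1L, 2L), 40 * 30, TRUE), 40, 30)
  tot <- matrix(rpois(40 * 30, 8), 40, 30)
  mc <- matrix(rbinom(40 * 30, tot, 0.5), 40, 30)
  f1 <- infer_f1_epigenotype(mc, tot, anc, min_individuals = 2L)
  f1_sw <- infer_f1_epigenotype(mc, tot, 2L - anc, min_individuals = 2L)
  expect_equal(f1$n_state, f1_sw$s_state)
  expect_equal(f1$s_state, f1_sw$n_state)
})

test_that("per-site ancestry interpolation uses nearest marker and flags discordant flanks", {
  map <- data.table::data.table(marker = c("a", "b"), chrom = "chr1",
                                bp = c(100L, 200L), cM = c(0, 1))
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(90L, 120L, 180L, 210L))
  ms <- matrix(c("NN", "NN",   # individual 1: concordant flanks
                 "NN", "SS"),  # individual 2: discordant
               2, 2)
  got <- ancestry_at_sites(ms, map, sites)
  expect_equal(got[, 1], rep(2L, 4))
  # outside the marker span the single nearest marker decides
  expect_equal(got[, 2], c(2L, NA, NA, 0L))
})

test_that("simulated F1 classes are recovered and segregate Mendelian", {
  set.seed(52)
  # somatic rates off: the Mendelian expectation is exactly 50% only for
  # pure inheritance (losses shift the NS pool to 0.5 * (1 - loss_rate))
  cfg <- tiny_cfg(n_sites = 10000L, n_f2 = 80L, coverage_mean = 5,
                  nonconversion_rate = 0, loss_rate_base = 0,
                  gain_rate_base = 0)
  scen <- simulate_scenario(cfg)
  truth <- scen$truth
  f1 <- infer_f1_epigenotype(scen$reads$mc, scen$reads$tot,
                             truth$site_n_alleles)
  true_sum <- truth$f1_n_allele + truth$f1_s_allele
  true_class <- c("00", "01", "11")[true_sum + 1L]
  called <- f1$class != "ambiguous"
  expect_gt(mean(called), 0.95)
  expect_gte(mean(f1$class[called] == true_class[called]), 0.99)
  # Mendelian check: NS individuals at het sites show ~50% methylation
  mend <- check_mendelian(scen$reads$mc, scen$reads$tot, f1,
                          truth$site_n_alleles)
  het_ns <- mend[class == "01" & ancestry == "NS"]
  expect_gt(het_ns$total_reads, 1000)
  expect_lt(abs(het_ns$level - 0.5), 0.02)
  # 00 sites stay near 0 across ancestries (gains + non-conversion bound)
  lvl00 <- mend[class == "00"]$level
  expect_true(all(lvl00 <= cfg$gain_rate_base + 0.003 + 0.005))
  # empty het class gives an empty row set, not an error
  f1_no_het <- f1[class != "01"]
  mend2 <- check_mendelian(scen$reads$mc[f1$class != "01", ],
                           scen$reads$tot[f1$class != "01", ], f1_no_het,
                           truth$site_n_alleles[f1$class != "01", ])
  expect_equal(mend2[class == "01"]$total_reads, rep(0, 3))
})

test_that("non-CG outlier genes are excluded at 2 SD", {
  gl_same <- data.table::data.table(gene = paste0("g", 1:20), line = "N",
                                    mCHG = 0.02, mCHH = 0.01)
  expect_equal(filter_gbm_genes(gl_same)$retained, paste0("g", 1:20))
  set.seed(53)
  n <- 1000L
  chg <- rnorm(n, 0.02, 0.004)
  planted <- sample(n, 50)
  chg[planted] <- 0.02 + 5.8 * 0.004   # ~5 SD after variance inflation
  gl <- data.table::data.table(gene = paste0("g", 1:n), line = "N",
                               mCHG = chg, mCHH = rnorm(n, 0.01, 0.002))
  res <- filter_gbm_genes(gl)
  expect_true(all(paste0("g", planted) %in% res$excluded$gene))
  # false exclusions near the one-sided normal tail expectation (~2.3%)
  false_excl <- setdiff(res$excluded[context == "mCHG"]$gene,
                        paste0("g", planted))
  expect_lt(length(false_excl) / (n - 50), 0.06)
  # a single extreme outlier is excluded
  gl1 <- data.table::data.table(gene = paste0("g", 1:50), line = "S",
                                mCHG = c(rnorm(49, 0.02, 0.002), 0.2),
                                mCHH = 0.01)
  expect_false("g50" %in% filter_gbm_genes(gl1)$retained)
})
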