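test_that("eligibility follows the inherited-diplotype rule table", {
  f1 <- make_f1(
    n_state = c("unmethylated", "methylated", "unmethylated", "methylated",
                "ambiguous"),
    s_state = c("unmethylated", "methylated", "methylated", "unmethylated",
                "methylated"))
  # classes: 00, 11, 01 (N unmeth), 01 (N meth), ambiguous
  anc <- matrix(c(2L, 1L, 0L), 5, 3, byrow = TRUE)  # ind: NN, NS, SS
  g <- eligible_sites(f1, anc, "gain")
  l <- eligible_sites(f1, anc, "loss")
  # class 00: gains for every ancestry, including NS
  expect_equal(g[1, ], c(TRUE, TRUE, TRUE))
  expect_equal(l[1, ], c(FALSE, FALSE, FALSE))
  # class 11: losses everywhere
  expect_equal(l[2, ], c(TRUE, TRUE, TRUE))
  expect_equal(g[2, ], c(FALSE, FALSE, FALSE))
  # het with N unmethylated: gains only in NN; losses only in SS
  expect_equal(g[3, ], c(TRUE, FALSE, FALSE))
  expect_equal(l[3, ], c(FALSE, FALSE, TRUE))
  # het with N methylated: mirrored
  expect_equal(g[4, ], c(FALSE, FALSE, TRUE))
  expect_equal(l[4, ], c(TRUE, FALSE, FALSE))
  # ambiguous sites never eligible; unknown ancestry never eligible
  expect_false(any(g[5, ]) || any(l[5, ]))
  anc_na <- matrix(NA_integer_, 5, 3)
  expect_false(any(eligible_sites(f1, anc_na, "gain")))
  # gain and loss cells are disjoint
  expect_false(any(g & l))
})

test_that("deviations are count-weighted averages", {
  f1 <- make_f1(rep("unmethylated", 2), rep("unmethylated", 2))
  anc <- matrix(2L, 2, 1)
  mc <- matrix(c(1L, 0L), 2, 1)
  tot <- matrix(c(10L, 30L), 2, 1)
  dev <- compute_deviations(mc, tot, eligible_sites(f1, anc, "gain"),
                            rep("w1", 2), "gain")
  expect_equal(dev$deviation, 1 / 40)

  f1l <- make_f1(rep("methylated", 2), rep("methylated", 2))
  mcl <- matrix(c(9L, 10L), 2, 1)
  totl <- matrix(10L, 2, 1)
  devl <- compute_deviations(mcl, totl, eligible_sites(f1l, anc, "loss"),
                             rep("w1", 2), "loss")
  expect_equal(devl$deviation, 1 / 20)
  # region with zero eligible coverage is absent, not zero
  dev0 <- compute_deviations(mc, tot, matrix(FALSE, 2, 1), rep("w1", 2),
                             "gain")
  expect_equal(nrow(dev0), 0L)
})

test_that("merging windows count-weighted reproduces the combined window", {
  set.seed(61)
  n <- 200L; m <- 15L
  mc <- matrix(rbinom(n * m, 10, 0.1), n, m)
  tot <- matrix(10L, n, m)
  elig <- matrix(runif(n * m) < 0.8, n, m)
  two <- rep(c("a", "b"), each = n / 2)
  one <- rep("ab", n)
  d2 <- compute_deviations(mc, tot, elig, two, "loss")
  d1 <- compute_deviations(mc, tot, elig, one, "loss")
  merged <- d2[, .(deviation = 1 - sum(mc_sum) / sum(total_sum)),
               by = individual]
  cmp <- merge(merged, d1, by = "individual")
  expect_equal(cmp$deviation.x, cmp$deviation.y)
})

test_that("stratified ratios are null-calibrated when no effect is planted", {
  set.seed(62)
  n <- 4000L; m <- 60L
  mc <- matrix(rbinom(n * m, 8, 0.07), n, m)
  tot <- matrix(8L, n, m)
  elig <- matrix(TRUE, n, m)
  strata <- sample(c("x", "y"), n, TRUE)
  ss <- stratified_summary(mc, tot, elig, strata, "loss", n_boot = 300L,
                           seed = 1)
  r <- stratum_ratio(ss, "x", "y")
  expect_lt(abs(r$ratio - 1), 0.05)
  expect_true(r$ci[1] <= 1 && 1 <= r$ci[2])
})

test_that("distance to nearest methylated site excludes self", {
  sites <- data.table::data.table(chrom = "chr1", pos = c(1010L, 1500L),
                                  deviation = c(0.2, 0.4))
  meth <- data.table::data.table(chrom = "chr1", pos = 1000L)
  prof <- distance_profile(sites, meth, max_bp = 1000L, bins = 10L)
  expect_equal(sum(prof$n), 2L)
  expect_equal(prof$bin_mid[1], 50)   # distance 10 lands in the first bin
  # a methylated focal site at the same position must not yield distance 0
  sites2 <- data.table::data.table(chrom = "chr1",
                                   pos = c(1000L, 1300L),
                                   deviation = 0.1)
  meth2 <- data.table::data.table(chrom = "chr1", pos = c(1000L, 1300L))
  prof2 <- distance_profile(sites2, meth2, max_bp = 1000L, bins = 10L)
  expect_equal(prof2$bin_mid, 350)    # both at distance 300, never 0
  # chromosome without methylated sites is skipped
  meth3 <- data.table::data.table(chrom = "chr2", pos = 1L)
  expect_equal(nrow(distance_profile(sites, meth3[0], max_bp = 1000L)), 0L)
})

test_that("planted distance-decaying gains show up in the profile", {
  set.seed(63)
  mpos <- sort(sample(1:1000000, 500))
  gpos <- setdiff(sort(sample(1:1000000, 4000)), mpos)
  d <- vapply(gpos, function(p) min(abs(p - mpos)), numeric(1))
  dev <- ifelse(d <= 30, 0.02, 0.002) + runif(length(gpos), 0, 1e-4)
  prof <- distance_profile(
    data.table::data.table(chrom = "chr1", pos = gpos, deviation = dev),
    data.table::data.table(chrom = "chr1", pos = mpos),
    max_bp = 300L, bins = 10L)
  near <- prof[bin_mid < 30]$median
  far <- prof[bin_mid > 60]$median
  expect_gt(min(near), max(far))
})

test_that("allelic difference correlation behaves at the extremes", {
  x <- seq(0.01, 0.5, length.out = 50)
  res <- allelic_difference_correlation(x, rep(0, 50), x * 2, rep(0, 50))
  expect_equal(res$rho, 1)
  set.seed(64)
  res0 <- allelic_difference_correlation(runif(1000), runif(1000),
                                         runif(1000), runif(1000))
  expect_lt(abs(res0$rho), 0.08)
  expect_error(allelic_difference_correlation(1:5, 1:5, 1:5, 1:5),
               "fewer than 10")
})

test_that("genome autocorrelation separates iid from smoothed signals", {
  set.seed(65)
  win <- data.table::data.table(
    chrom = rep(c("chr1", "chr2"), each = 100),
    start = rep(seq(0, 99) * 500000L, 2),
    value = rnorm(200))
  ac <- genome_autocorrelation(win, max_lag = 3L)
  expect_lt(abs(ac[lag == 1]$correlation), 0.15)
  sm <- data.table::copy(win)
  sm[, value := as.numeric(stats::filter(value, rep(1 / 5, 5), sides = 2)),
     by = chrom]
  ac_sm <- genome_autocorrelation(sm[!is.na(value)], max_lag = 3L)
  expect_gt(ac_sm[lag == 1]$correlation, 0.5)
  # one window per chromosome: nothing to correlate
  single <- data.table::data.table(chrom = c("chr1", "chr2"),
                                   start = 0L, value = c(1, 2))
  expect_equal(nrow(genome_autocorrelation(single)), 0L)
})

test_that("window assignment tiles from position 1 and keeps partial windows", {
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(1L, 500000L, 500001L, 1200000L))
  w <- assign_windows(sites)
  expect_equal(w, c("chr1:0-500000", "chr1:0-500000",
                    "chr1:500000-1000000", "chr1:1000000-1500000"))
})
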