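test_that("F2 transition matrix matches gamete-pair enumeration", {
  expect_equal(f2_transition_matrix(0), diag(3), ignore_attr = TRUE)
  expect_equal(unname(f2_transition_matrix(0.5)),
               matrix(c(0.25, 0.5, 0.25), 3, 3, byrow = TRUE))
  # independent oracle: enumerate the two gametes switching independently
  enum_row <- function(from_n, r) {
    # from_n = N alleles in current state; each allele switches w.p. r
    probs <- c(0, 0, 0)
    for (a1 in 0:1) for (a2 in 0:1) {
      p <- (if (a1) r else 1 - r) * (if (a2) r else 1 - r)
      n_new <- (if (from_n >= 1) 1 - a1 else a1) +
        (if (from_n == 2) 1 - a2 else a2)
      probs[3 - n_new] <- probs[3 - n_new] + p
    }
    probs
  }
  for (r in c(0.01, 0.1, 0.37)) {
    m <- f2_transition_matrix(r)
    expect_equal(unname(m[1, ]), enum_row(2, r))
    expect_equal(unname(m[2, ]), enum_row(1, r))
    expect_equal(unname(m[3, ]), enum_row(0, r))
    expect_equal(unname(rowSums(m)), rep(1, 3))
    # N/S relabelling symmetry
    expect_equal(m[1, ], rev(m[3, ]), ignore_attr = TRUE)
  }
  expect_equal(unname(f2_transition_matrix(0.1)[1, ]), c(0.81, 0.18, 0.01))
  expect_error(f2_transition_matrix(0.7), "0.5")
  expect_error(f2_transition_matrix(-0.1), "0.5")
})

test_that("emission log-likelihoods have their closed forms", {
  expect_equal(emission_loglik(5, 0, "NN"), 5 * log(0.99))
  expect_equal(emission_loglik(0, 0, "SS"), 0)
  expect_equal(emission_loglik(3, 3, "NS"), lchoose(6, 3) + 6 * log(0.5))
  expect_equal(emission_loglik(2, 8, "SS", 0.02),
               lchoose(10, 2) + 2 * log(0.02) + 8 * log(0.98))
  expect_error(emission_loglik(1, 1, "NN", error_rate = 0.6), "error_rate")
  expect_error(emission_loglik(1, 1, "NN", error_rate = 0), "error_rate")
})

test_that("HMM is confident on dense error-free data and normalised", {
  map <- data.table::data.table(marker = sprintf("m%02d", 1:30),
                                chrom = "chr1", bp = (1:30) * 1e5,
                                cM = (1:30) * 0.5)
  path <- infer_ancestry(rep(10L, 30), rep(0L, 30), map)
  expect_true(all(path$map_state == "NN"))
  expect_true(all(path$posterior[, "NN"] > 0.999))
  expect_equal(unname(rowSums(path$posterior)), rep(1, 30),
               tolerance = 1e-9)
  expect_equal(path$crossovers, 0L)
  # MAP state has maximal posterior
  expect_true(all(path$map_state ==
                    colnames(path$posterior)[max.col(path$posterior)]))
})

test_that("HMM recovers simulated ancestry and respects label symmetry", {
  set.seed(41)
  cfg <- tiny_cfg(n_sites = 50, n_f2 = 30L, chrom_length_bp = 24000000L,
                  marker_spacing_bp = 30000L, marker_coverage_mean = 1)
  truth <- simulate_f2(cfg, simulate_parents(cfg))
  rd <- simulate_reads(cfg, truth)
  res <- infer_ancestry_all(rd$marker_n, rd$marker_s, truth$map)
  truth_state <- matrix(c("SS", "NS", "NN")[truth$marker_n_alleles + 1L],
                        nrow(truth$map))
  acc <- mean(res$map_state == truth_state)
  expect_gte(acc, 0.98)
  # marginal MAP-state frequencies near (0.25, 0.5, 0.25) per marker
  se <- sqrt(0.25 * 0.75 / 30)
  for (m in c(10L, 400L)) {
    expect_lt(abs(mean(res$map_state[m, ] == "NN") - 0.25), 4 * se)
  }
  # swapping N and S counts maps NN <-> SS exactly
  p1 <- infer_ancestry(rd$marker_n[, 1], rd$marker_s[, 1], truth$map)
  p2 <- infer_ancestry(rd$marker_s[, 1], rd$marker_n[, 1], truth$map)
  swap <- c(NN = "SS", NS = "NS", SS = "NN")
  expect_equal(unname(swap[p1$map_state]), p2$map_state)
  # Viterbi path vs forward-backward argmax: internal consistency
  fb <- colnames(p1$posterior)[max.col(p1$posterior)]
  expect_gte(mean(fb == p1$map_state), 0.99)
})

test_that("likelihood grows with depth of consistent evidence", {
  map <- data.table::data.table(marker = sprintf("m%02d", 1:10),
                                chrom = "chr1", bp = (1:10) * 1e5,
                                cM = (1:10) * 0.5)
  ll <- vapply(c(1L, 3L, 8L), function(depth) {
    infer_ancestry(rep(depth, 10), rep(0L, 10), map)$posterior[5, "NN"]
  }, numeric(1))
  expect_true(all(diff(ll) >= 0))
  expect_error(infer_ancestry(1:3, 1:3, map), "markers")
})

test_that("duplicate-marker filter keeps one representative per run", {
  g <- matrix("NN", 6, 4, dimnames = list(paste0("m", 1:6), NULL))
  expect_equal(filter_markers(g), "m1")
  g2 <- matrix(sample(c("NN", "NS", "SS"), 24, TRUE), 6, 4,
               dimnames = list(paste0("m", 1:6), NULL))
  while (any(duplicated(apply(g2, 1, paste, collapse = "")))) {
    g2 <- matrix(sample(c("NN", "NS", "SS"), 24, TRUE), 6, 4,
                 dimnames = list(paste0("m", 1:6), NULL))
  }
  expect_equal(filter_markers(g2), paste0("m", 1:6))
  # 10 blocks of 5 duplicated rows -> 10 retained
  set.seed(42)
  blocks <- matrix(sample(c("NN", "NS", "SS"), 10 * 8, TRUE), 10, 8)
  big <- blocks[rep(1:10, each = 5), ]
  rownames(big) <- sprintf("m%03d", 1:50)
  expect_equal(filter_markers(big), sprintf("m%03d", seq(1, 50, by = 5)))
})

test_that("heterozygosity scan recovers a planted block", {
  set.seed(43)
  pos <- seq(1000L, 3000000L, by = 1000L)
  call <- rep("hom", length(pos))
  block <- pos >= 1000000L & pos < 1500000L
  call[block] <- ifelse(runif(sum(block)) < 0.8, "het", "hom")
  calls <- data.table::data.table(chrom = "chr1", pos = pos, call = call)
  hits <- heterozygosity_scan(calls)
  expect_equal(nrow(hits), 1L)
  expect_lt(abs(hits$start - 1000000L), 300000L + 1)
  expect_lt(abs(hits$end - 1500000L), 300000L + 1)
  expect_gt(hits$het_fraction, 0.5)
  # all-homozygous input and an impossible threshold give empty reports
  calls_hom <- data.table::data.table(chrom = "chr1", pos = pos,
                                      call = "hom")
  expect_equal(nrow(heterozygosity_scan(calls_hom)), 0L)
  expect_equal(nrow(heterozygosity_scan(calls, threshold = 1)), 0L)
})
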