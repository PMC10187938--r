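#' Haley-Knott genotype covariates from ancestry posteriors
#'
#' @param posterior Matrix (individuals x 3) of (NN, NS, SS) posterior
#'   probabilities, rows summing to 1.
#' @return List: `a` (additive, p_NN - p_SS in \[-1, 1\]), `d` (dominance,
#'   p_NS in \[0, 1\]).
#' @export
genotype_design <- function(posterior) {
  posterior <- as.matrix(posterior)
  stopifnot(ncol(posterior) == 3L)
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    stop("ancestry posteriors must sum to 1 per individual")
  }
  list(a = posterior[, 1] - posterior[, 3], d = posterior[, 2])
}

# QR factors for one scan: per-marker model matrices are fixed across
# phenotypes and rotations, so their thin-Q matrices are cached.
hk_precompute <- function(a, d, temperature, model = c("full", "additive"),
                          marker_covariates = NULL) {
  model <- match.arg(model)
  n <- nrow(a)
  Tf <- factor(temperature)
  X0 <- model.matrix(~Tf)
  if (!is.null(marker_covariates)) X0 <- cbind(X0, marker_covariates)
  q0 <- qr(X0)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  M <- ncol(a)
  Qs <- vector("list", M)
  skipped <- logical(M)
  for (m in seq_len(M)) {
    X <- cbind(X0, a = a[, m], d = d[, m])
    if (model == "full") {
      TT <- model.matrix(~Tf)[, -1, drop = FALSE]
      X <- cbind(X, a[, m] * TT, d[, m] * TT)
    }
    qx <- qr(X)
    if (qx$rank <= q0$rank) {
      skipped[m] <- TRUE
      Qs[[m]] <- Q0
    } else {
      Qs[[m]] <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    }
  }
  # stack all thin-Q factors so a scan is a single BLAS call
  Qall <- do.call(cbind, Qs)
  idx <- rep(seq_len(M), vapply(Qs, ncol, integer(1)))
  list(Q0 = Q0, Qall = Qall, idx = idx, skipped = skipped, n = n,
       model = model)
}

# LOD matrix (markers x phenotypes) given cached QR factors.
hk_lod <- function(pre, Y) {
  Y <- as.matrix(Y)
  cs <- colSums(Y^2)
  rss0 <- cs - colSums(crossprod(pre$Q0, Y)^2)
  fit_ss <- rowsum(crossprod(pre$Qall, Y)^2, pre$idx)
  rss <- matrix(cs, max(pre$idx), ncol(Y), byrow = TRUE) - fit_ss
  lod <- pre$n / 2 * log10(pmax(matrix(rss0, max(pre$idx), ncol(Y),
                                       byrow = TRUE), 1e-300) /
                             pmax(rss, 1e-300))
  pmax(lod, 0)
}

#' Haley-Knott scan of one window phenotype
#'
#' Regresses a window-deviation phenotype on expected genotype covariates at
#' each marker. The null model is `y ~ 1 + T` (temperature cofactor, plus any
#' marker covariates for composite interval mapping); the additive model adds
#' the additive and dominance covariates; the full model additionally allows
#' genotype-by-temperature interaction. `LOD = (n/2) log10(RSS_null /
#' RSS_model)`; the interaction LOD is the difference of the full and
#' additive model LODs.
#'
#' @param y Phenotype vector (one value per individual; `NA` rows dropped).
#' @param a,d Matrices (individuals x markers) of additive/dominance
#'   covariates from [genotype_design()].
#' @param temperature Factor/character of growth temperatures.
#' @param marker_covariates Optional numeric matrix of additional covariates
#'   included in all models (composite interval mapping).
#' @param min_n Minimum non-missing individuals.
#' @return `data.table`: marker index, lod_full, lod_additive,
#'   lod_interaction, skipped.
#' @export
scan_window <- function(y, a, d, temperature, marker_covariates = NULL,
                        min_n = 30L) {
  ok <- !is.na(y)
  if (sum(ok) < min_n) {
    stop("phenotype observed for ", sum(ok), " individuals; need >= ", min_n)
  }
  a <- as.matrix(a)[ok, , drop = FALSE]
  d <- as.matrix(d)[ok, , drop = FALSE]
  temperature <- temperature[ok]
  if (!is.null(marker_covariates)) {
    marker_covariates <- as.matrix(marker_covariates)[ok, , drop = FALSE]
  }
  y <- y[ok]
  pre_f <- hk_precompute(a, d, temperature, "full", marker_covariates)
  pre_a <- hk_precompute(a, d, temperature, "additive", marker_covariates)
  if (any(pre_f$skipped)) {
    warning("skipped ", sum(pre_f$skipped), " singular marker design(s)")
  }
  lod_f <- hk_lod(pre_f, y)[, 1]
  lod_a <- hk_lod(pre_a, y)[, 1]
  data.table::data.table(marker = seq_len(ncol(a)),
                         lod_full = lod_f, lod_additive = lod_a,
                         lod_interaction = pmax(0, lod_f - lod_a),
                         skipped = pre_f$skipped)
}

#' Sum LOD scores across window phenotypes
#'
#' Trans-acting modifiers affect deviations genome-wide, so evidence is
#' aggregated by summing per-window LOD scores at each marker.
#'
#' @param scans List of scan `data.table`s from [scan_window()], all on the
#'   same marker grid.
#' @param statistic Which LOD column to sum.
#' @return `data.table`: marker, lod_sum, plus a `contributions` attribute
#'   (markers x windows matrix) for effect localisation.
#' @export
aggregate_scan <- function(scans, statistic = "lod_full") {
  m <- vapply(scans, nrow, integer(1))
  if (length(unique(m)) != 1L) {
    stop("scans use different marker grids: ", paste(unique(m), collapse = ", "))
  }
  contrib <- vapply(scans, function(s) s[[statistic]], numeric(m[1]))
  if (m[1] == 1L) contrib <- matrix(contrib, nrow = 1L)
  out <- data.table::data.table(marker = scans[[1]]$marker,
                                lod_sum = rowSums(contrib))
  data.table::setattr(out, "contributions", contrib)
  out
}

#' Significance threshold for the aggregate LOD by genome rotation
#'
#' Builds an empirical null for the genome-wide maximum of the summed LOD.
#' Each replicate circularly rotates the assignment of phenotype vectors to
#' genotype vectors across individuals (within temperature groups, so the
#' phenotype-temperature link is preserved), recomputes the full aggregate
#' scan, and records its maximum. Rotation preserves marker LD and the
#' correlation structure among window phenotypes while breaking
#' genotype-phenotype association. Individual-label permutation is available
#' as an alternative.
#'
#' @param Y Matrix (individuals x windows) of window phenotypes.
#' @param a,d Genotype covariate matrices (individuals x markers).
#' @param temperature Temperature factor.
#' @param n_rotations Number of null replicates.
#' @param quantile_level Quantile of the max distribution used as threshold.
#' @param seed RNG seed (mandatory in the CLI).
#' @param method `"rotation"` (circular shift) or `"permutation"`.
#' @param statistic `"full"` or `"additive"` model LOD.
#' @return List: `threshold`, `maxima` (length `n_rotations`),
#'   `observed_max`, `observed` (aggregate scan of the unrotated data).
#' @export
rotation_threshold <- function(Y, a, d, temperature, n_rotations = 1000L,
                               quantile_level = 0.99, seed = NULL,
                               method = c("rotation", "permutation"),
                               statistic = c("full", "additive")) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  if (ncol(Y) < 10L) {
    stop("rotation needs >= 10 window phenotypes, got ", ncol(Y))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pre <- hk_precompute(a, d, temperature,
                       if (statistic == "full") "full" else "additive")
  agg <- function(Ym) rowSums(hk_lod(pre, Ym))
  obs <- agg(Y)
  groups <- split(seq_len(nrow(Y)), factor(temperature))
  maxima <- numeric(n_rotations)
  for (r in seq_len(n_rotations)) {
    idx <- seq_len(nrow(Y))
    for (g in groups) {
      ng <- length(g)
      if (ng < 2L) next
      if (method == "rotation") {
        off <- sample.int(ng - 1L, 1L)
        idx[g] <- g[((seq_len(ng) - 1L + off) %% ng) + 1L]
      } else {
        idx[g] <- g[sample.int(ng)]
      }
    }
    maxima[r] <- max(agg(Y[idx, , drop = FALSE]))
  }
  list(threshold = unname(quantile(maxima, quantile_level)),
       maxima = maxima, observed_max = max(obs),
       observed = data.table::data.table(marker = seq_along(obs),
                                         lod_sum = obs))
}

#' Variance partition for window deviations
#'
#' Fits the linear model
#' `y = G_cis + T + sum_i G_QTLi + G_cis x T + sum_i G_QTLi x T + e`
#' with categorical genotype factors and decomposes phenotypic variance into
#' per-term shares. Because the factors are correlated, shares use
#' sequential sums of squares averaged over admissible term orderings (each
#' interaction entering after both its main effects), the LMG-style
#' decomposition.
#'
#' @param y Phenotype vector.
#' @param cis Optional factor: local genotype (NN/NS/SS) at the window.
#' @param temperature Optional factor: growth temperature.
#' @param qtl Named list of factors: genotypes at identified QTL.
#' @param interactions Include genotype-by-temperature interactions.
#' @param max_orderings Cap on enumerated orderings (sampled beyond it).
#' @return List of class `variance_partition`: `shares` (named fractions,
#'   including `residual`), `total_explained`, `n`.
#' @export
variance_partition <- function(y, cis = NULL, temperature = NULL,
                               qtl = list(), interactions = TRUE,
                               max_orderings = 60L) {
  terms <- list()
  if (!is.null(cis)) terms$cis <- factor(cis)
  if (!is.null(temperature)) terms$T <- factor(temperature)
  if (length(qtl)) {
    if (is.null(names(qtl)) || any(names(qtl) == "")) {
      names(qtl) <- paste0("QTL", seq_along(qtl))
    }
    for (nm in names(qtl)) terms[[nm]] <- factor(qtl[[nm]])
  }
  if (!length(terms)) stop("no model terms supplied")
  ok <- complete.cases(y, as.data.frame(terms))
  y <- y[ok]
  terms <- lapply(terms, function(f) droplevels(factor(f[ok])))
  n <- length(y)

  mm <- lapply(terms, function(f) model.matrix(~f)[, -1, drop = FALSE])
  inter <- list()
  if (interactions && "T" %in% names(terms)) {
    for (nm in setdiff(names(terms), "T")) {
      ia <- mm[[nm]][, rep(seq_len(ncol(mm[[nm]])), ncol(mm$T)),
                     drop = FALSE] *
        mm$T[, rep(seq_len(ncol(mm$T)), each = ncol(mm[[nm]])), drop = FALSE]
      inter[[paste0(nm, ":T")]] <- ia
    }
  }
  blocks <- c(mm, inter)
  parents <- lapply(names(blocks), function(nm) {
    if (grepl(":", nm, fixed = TRUE)) strsplit(nm, ":", fixed = TRUE)[[1]]
    else character(0)
  })
  names(parents) <- names(blocks)

  X_full <- do.call(cbind, c(list(matrix(1, n, 1)), unname(blocks)))
  qf <- qr(X_full)
  if (qf$rank < ncol(X_full)) {
    dropped <- setdiff(seq_len(ncol(X_full)), qf$pivot[seq_len(qf$rank)])
    sizes <- vapply(blocks, ncol, integer(1))
    owner <- rep(names(blocks), sizes)[pmax(dropped - 1L, 1L)]
    stop("aliased model terms (collinear): ",
         paste(unique(owner), collapse = ", "))
  }

  k <- length(blocks)
  admissible <- function(ord) {
    nm <- names(blocks)[ord]
    for (i in seq_along(nm)) {
      pp <- parents[[nm[i]]]
      if (length(pp) && !all(pp %in% nm[seq_len(i - 1L)])) return(FALSE)
    }
    TRUE
  }
  perms <- all_permutations(k)
  perms <- perms[vapply(perms, admissible, logical(1))]
  if (length(perms) > max_orderings) {
    perms <- perms[sample.int(length(perms), max_orderings)]
  }

  tss <- sum((y - mean(y))^2)
  ss_acc <- setNames(numeric(k), names(blocks))
  for (ord in perms) {
    X <- matrix(1, n, 1)
    rss_prev <- tss
    for (bi in ord) {
      X <- cbind(X, blocks[[bi]])
      fit <- lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      ss_acc[bi] <- ss_acc[bi] + (rss_prev - rss)
      rss_prev <- rss
    }
  }
  shares <- ss_acc / length(perms) / tss
  rss_full <- sum(lm.fit(X_full, y)$residuals^2)
  shares <- c(shares, residual = rss_full / tss)
  structure(list(shares = shares,
                 total_explained = 1 - rss_full / tss, n = n),
            class = "variance_partition")
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Simulate a window-deviation phenotype with one additive QTL
#'
#' Phenotype `y = u + e` where `u` is the centred additive genotype coding
#' (N-allele count minus one) and Gaussian noise is scaled so the QTL
#' explains `ve` of the phenotypic variance in expectation
#' (`Var(u) = 1/2` in an F2).
#'
#' @param u Genotype coding vector (k - 1 for k N alleles).
#' @param ve Target variance explained, in (0, 1).
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype_qtl <- function(u, ve) {
  stopifnot(ve > 0, ve < 1)
  u + rnorm(length(u), sd = sqrt(0.5 * (1 - ve) / ve))
}
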