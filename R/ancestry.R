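ANCESTRY_STATES <- c("NN", "NS", "SS")

#' F2 ancestry transition matrix
#'
#' Transition probabilities between local-ancestry diplotypes (NN, NS, SS)
#' across an interval with recombination fraction `r`, assuming independent
#' meioses in the two F1 gametes.
#'
#' @param r Recombination fraction in \[0, 0.5\].
#' @return A 3x3 row-stochastic matrix ordered (NN, NS, SS).
#' @export
f2_transition_matrix <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("recombination fraction must lie in [0, 0.5]")
  }
  nn <- c((1 - r)^2, 2 * r * (1 - r), r^2)
  ns <- c(r * (1 - r), (1 - r)^2 + r^2, r * (1 - r))
  m <- rbind(nn, ns, rev(nn))
  dimnames(m) <- list(ANCESTRY_STATES, ANCESTRY_STATES)
  m
}

#' Emission log-likelihood of marker allele counts
#'
#' Binomial model over the two parental alleles: given ancestry state, a read
#' reports the northern allele with probability `1 - error_rate` (NN), `0.5`
#' (NS) or `error_rate` (SS). Zero-depth markers contribute log 1 = 0.
#'
#' @param n_reads Northern-allele read counts (vector).
#' @param s_reads Southern-allele read counts (vector).
#' @param state One of `"NN"`, `"NS"`, `"SS"`.
#' @param error_rate Per-read genotyping error, strictly inside (0, 0.5).
#' @return Log-likelihood vector (one value per marker).
#' @export
emission_loglik <- function(n_reads, s_reads, state, error_rate = 0.01) {
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must lie strictly inside (0, 0.5)")
  }
  state <- match.arg(state, ANCESTRY_STATES)
  p <- switch(state, NN = 1 - error_rate, NS = 0.5, SS = error_rate)
  tot <- n_reads + s_reads
  ll <- lchoose(tot, n_reads) + n_reads * log(p) + s_reads * log1p(-p)
  ll[tot == 0] <- 0
  ll
}

# Haldane map function inverse: cM distance -> recombination fraction.
haldane_r <- function(d_cM) {
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Infer F2 local ancestry with a three-state HMM
#'
#' Forward-backward posteriors and a Viterbi maximum a posteriori path over
#' the marker grid for one individual. Transitions come from adjacent-marker
#' cM distances via the Haldane map function; emissions from
#' [emission_loglik()]. The initial distribution is the F2 expectation
#' (1/4, 1/2, 1/4). Chromosomes are independent (transition r = 0.5 is never
#' crossed; each chromosome restarts at the initial distribution).
#'
#' @param n_reads,s_reads Per-marker allele read counts, in map order.
#' @param map `data.table` with columns marker, chrom, bp, cM (sorted).
#' @param error_rate Per-read genotyping error.
#' @return List of class `ancestry_path`: `map_state` (character),
#'   `posterior` (markers x 3 matrix), `crossovers` (MAP state changes),
#'   `loglik`.
#' @export
infer_ancestry <- function(n_reads, s_reads, map, error_rate = 0.01) {
  M <- nrow(map)
  if (length(n_reads) != M || length(s_reads) != M) {
    stop("allele counts and map differ in length: ", length(n_reads),
         " vs ", M, " markers")
  }
  emis <- cbind(emission_loglik(n_reads, s_reads, "NN", error_rate),
                emission_loglik(n_reads, s_reads, "NS", error_rate),
                emission_loglik(n_reads, s_reads, "SS", error_rate))
  init <- c(0.25, 0.5, 0.25)
  new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-M])
  d <- c(0, pmax(0, diff(map$cM)))
  d[new_chrom] <- 0
  trans <- lapply(seq_len(M), function(i) {
    if (new_chrom[i]) NULL else f2_transition_matrix(haldane_r(d[i]))
  })

  # scaled forward-backward
  e <- exp(emis - apply(emis, 1, max))
  fwd <- matrix(0, M, 3)
  scl <- numeric(M)
  logmax <- apply(emis, 1, max)
  for (i in seq_len(M)) {
    pri <- if (new_chrom[i]) init else as.vector(fwd[i - 1, ] %*% trans[[i]])
    a <- pri * e[i, ]
    scl[i] <- sum(a)
    fwd[i, ] <- a / scl[i]
  }
  loglik <- sum(log(scl) + logmax)
  bwd <- matrix(0, M, 3)
  bwd[M, ] <- 1
  for (i in seq(M - 1, 1)) {
    if (new_chrom[i + 1]) {
      bwd[i, ] <- 1
    } else {
      b <- trans[[i + 1]] %*% (e[i + 1, ] * bwd[i + 1, ])
      bwd[i, ] <- b / max(b)
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)
  colnames(post) <- ANCESTRY_STATES

  # Viterbi in log space
  lt <- lapply(trans, function(m) if (is.null(m)) NULL else log(m))
  delta <- matrix(-Inf, M, 3)
  psi <- matrix(0L, M, 3)
  linit <- log(init)
  for (i in seq_len(M)) {
    if (new_chrom[i]) {
      delta[i, ] <- linit + emis[i, ]
    } else {
      for (s in 1:3) {
        cand <- delta[i - 1, ] + lt[[i]][, s]
        psi[i, s] <- which.max(cand)
        delta[i, s] <- cand[psi[i, s]] + emis[i, s]
      }
    }
  }
  path <- integer(M)
  for (i in rev(seq_len(M))) {
    if (i == M || new_chrom[i + 1]) path[i] <- which.max(delta[i, ])
    else path[i] <- psi[i + 1, path[i + 1]]
  }
  map_state <- ANCESTRY_STATES[path]
  xo <- sum(map_state[-1] != map_state[-M] & !new_chrom[-1])
  structure(list(map_state = map_state, posterior = post,
                 crossovers = xo, loglik = loglik),
            class = "ancestry_path")
}

#' Infer ancestry for all individuals of a population
#'
#' @param marker_n,marker_s Matrices (markers x individuals) of allele read
#'   counts.
#' @param map Marker map (see [infer_ancestry()]).
#' @param error_rate Per-read genotyping error.
#' @return List with `map_state` (markers x individuals character matrix)
#'   and `paths` (list of `ancestry_path`).
#' @export
infer_ancestry_all <- function(marker_n, marker_s, map, error_rate = 0.01) {
  n_ind <- ncol(marker_n)
  paths <- vector("list", n_ind)
  states <- matrix(NA_character_, nrow(map), n_ind)
  for (j in seq_len(n_ind)) {
    paths[[j]] <- infer_ancestry(marker_n[, j], marker_s[, j], map, error_rate)
    states[, j] <- paths[[j]]$map_state
  }
  list(map_state = states, paths = paths)
}

#' Collapse runs of markers with identical genotype columns
#'
#' Adjacent markers whose genotype data are identical across all individuals
#' carry no extra linkage information; one representative per run is kept.
#'
#' @param geno Matrix (markers x individuals) of genotype calls; rownames are
#'   marker ids.
#' @return Character vector of retained marker ids (or indices when rownames
#'   are absent).
#' @export
filter_markers <- function(geno) {
  if (nrow(geno) == 0) return(character(0))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  key <- apply(geno, 1, paste, collapse = "\r")
  keep <- c(TRUE, key[-1] != key[-length(key)])
  ids[keep]
}

#' Scan an inbred line for residual heterozygosity
#'
#' Tiles the genome in windows and reports merged runs of windows whose
#' fraction of heterozygous SNP calls exceeds a threshold, provided the
#' merged run is at least one window long.
#'
#' @param calls `data.table` with columns chrom, pos, call (values `"hom"`,
#'   `"het"`, `"missing"`).
#' @param window_bp Window size (default 300 kb).
#' @param threshold Minimum heterozygous fraction (among non-missing calls)
#'   for a window to be flagged.
#' @return `data.table`: chrom, start, end, het_fraction (1-based inclusive
#'   intervals).
#' @export
heterozygosity_scan <- function(calls, window_bp = 300000L, threshold = 0.1) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0 || threshold >= 1) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), het_fraction = numeric()))
  }
  calls[, win := (pos - 1L) %/% as.integer(window_bp)]
  ws <- calls[call != "missing",
              .(het_fraction = mean(call == "het"), n = .N),
              by = .(chrom, win)]
  ws <- ws[het_fraction > threshold][order(chrom, win)]
  if (nrow(ws) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), het_fraction = numeric()))
  }
  # merge adjacent flagged windows
  ws[, grp := cumsum(c(1L, (diff(win) != 1L) |
                         (chrom[-1] != chrom[-.N]))), by = NULL]
  out <- ws[, .(chrom = chrom[1],
                start = win[1] * as.integer(window_bp) + 1L,
                end = (win[.N] + 1L) * as.integer(window_bp),
                het_fraction = sum(het_fraction * n) / sum(n)),
            by = grp]
  out[, grp := NULL]
  out[]
}
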