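#' Load a scenario directory into memory
#'
#' Reads the file set produced by [write_scenario()] (or equivalently
#' formatted real data): per-individual allc-style methylomes, parental
#' replicate methylomes, the marker allele-count table, the marker map and
#' the sample metadata.
#'
#' @param dir Scenario directory.
#' @return List of class `epi_dataset`: `sites`, `mc`, `tot`, `parent_mc`,
#'   `parent_tot`, `marker_n`, `marker_s`, `map`, `meta`.
#' @export
read_scenario <- function(dir) {
  need <- c("metadata.tsv", "map.tsv", "markers.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files)) {
    stop("scenario directory ", dir, " is missing: ",
         paste(missing_files, collapse = ", "))
  }
  meta <- data.table::fread(file.path(dir, "metadata.tsv"))
  map <- data.table::fread(file.path(dir, "map.tsv"))
  markers <- data.table::fread(file.path(dir, "markers.tsv"))

  read_counts <- function(name) {
    read_methylome(file.path(dir, paste0(name, ".allc.tsv")))
  }
  first <- read_counts(meta$individual[1])
  sites <- first[, .(chrom, pos, context)]
  n_sites <- nrow(sites)
  mc <- matrix(0L, n_sites, nrow(meta))
  tot <- matrix(0L, n_sites, nrow(meta))
  for (j in seq_len(nrow(meta))) {
    tbl <- if (j == 1L) first else read_counts(meta$individual[j])
    if (nrow(tbl) != n_sites) {
      stop("methylome ", meta$individual[j], " has ", nrow(tbl),
           " sites; expected ", n_sites)
    }
    mc[, j] <- tbl$mc_count
    tot[, j] <- tbl$total_count
  }
  parent_mc <- list(); parent_tot <- list()
  for (line in c("N", "S")) {
    files <- sort(list.files(dir, sprintf("^parent_%s_rep\\d+\\.allc\\.tsv$",
                                          line)))
    pm <- matrix(0L, n_sites, length(files))
    pt <- matrix(0L, n_sites, length(files))
    for (r in seq_along(files)) {
      tbl <- read_methylome(file.path(dir, files[r]))
      pm[, r] <- tbl$mc_count
      pt[, r] <- tbl$total_count
    }
    parent_mc[[line]] <- pm
    parent_tot[[line]] <- pt
  }
  data.table::setkey(markers, individual)
  marker_n <- matrix(0L, nrow(map), nrow(meta))
  marker_s <- matrix(0L, nrow(map), nrow(meta))
  for (j in seq_len(nrow(meta))) {
    mk <- markers[individual == meta$individual[j]]
    ord <- match(map$marker, mk$marker)
    if (anyNA(ord)) {
      stop("marker table for ", meta$individual[j],
           " is missing map markers: ",
           paste(head(map$marker[is.na(ord)], 3), collapse = ", "))
    }
    marker_n[, j] <- mk$n_reads[ord]
    marker_s[, j] <- mk$s_reads[ord]
  }
  structure(list(sites = sites, mc = mc, tot = tot,
                 parent_mc = parent_mc, parent_tot = parent_tot,
                 marker_n = marker_n, marker_s = marker_s,
                 map = map, meta = meta),
            class = "epi_dataset")
}

default_pipeline_config <- function() {
  list(cutoff = 0.5, min_coverage = 3L, min_individuals = 10L,
       nonconversion_rate = 0.003, nonconversion_alpha = 0.05,
       gain_max = 0.2, loss_max = 0.35, window_bp = 500000L,
       n_rotations = 1000L, n_null_reps = 200L, n_null_sites = 2000L,
       genotyping_error = 0.01, seed = 1L)
}

#' Run the full analysis pipeline on a scenario directory
#'
#' Stages, in dependency order: local-ancestry HMM, F1 epigenotype
#' inference, somatic gain/loss deviation matrices (genes not required;
#' 500-kb windows), binomial null-model variance check, Haley-Knott QTL scan
#' with rotation thresholds, and transgenerational epimutation rates. Every
#' output TSV carries a header comment with package version, configuration
#' hash and seed; `pipeline.log` records per-stage counts.
#'
#' @param scenario_dir Input directory (see [read_scenario()]).
#' @param out_dir Output directory.
#' @param config Named list overriding the defaults (cutoff, min_coverage,
#'   min_individuals, nonconversion_rate, nonconversion_alpha, gain_max,
#'   loss_max, window_bp, n_rotations, n_null_reps, n_null_sites,
#'   genotyping_error, seed), or the path of a YAML file with those fields.
#' @return Invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(scenario_dir, out_dir, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  set.seed(as.integer(cfg$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stamp <- sprintf("# epideviate %s | config %s | seed %d",
                   as.character(utils::packageVersion("epideviate")),
                   substr(digest_config(cfg), 1, 8), as.integer(cfg$seed))
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    data.table::fwrite(tbl, path, sep = "\t", append = TRUE,
                       col.names = TRUE)
    path
  }

  ds <- read_scenario(scenario_dir)
  logf("load: %d sites, %d individuals, %d markers", nrow(ds$sites),
       nrow(ds$meta), nrow(ds$map))

  anc <- infer_ancestry_all(ds$marker_n, ds$marker_s, ds$map,
                            cfg$genotyping_error)
  anc_tbl <- data.table::data.table(
    marker = rep(ds$map$marker, nrow(ds$meta)),
    individual = rep(ds$meta$individual, each = nrow(ds$map)),
    state = as.vector(anc$map_state))
  emit(anc_tbl, "ancestry.tsv")
  logf("ancestry: mean crossovers %.2f",
       mean(vapply(anc$paths, `[[`, numeric(1), "crossovers")))

  site_anc <- ancestry_at_sites(anc$map_state, ds$map, ds$sites)
  par_n <- infer_parental_state(ds$parent_mc$N, ds$parent_tot$N,
                                cfg$cutoff, cfg$min_coverage)
  par_s <- infer_parental_state(ds$parent_mc$S, ds$parent_tot$S,
                                cfg$cutoff, cfg$min_coverage)
  f1 <- infer_f1_epigenotype(ds$mc, ds$tot, site_anc, cfg$cutoff,
                             cfg$min_individuals, cfg$min_coverage)
  emit(cbind(ds$sites, f1[, .(n_state, s_state, class)],
             gp_n_state = par_n$state, gp_s_state = par_s$state),
       "epigenotype.tsv")
  logf("epigenotype: classes %s",
       paste(names(table(f1$class)), table(f1$class), collapse = " ",
             sep = "="))

  windows <- assign_windows(ds$sites, cfg$window_bp)
  mc_gain <- matrix(nonconversion_filter(ds$mc, ds$tot,
                                         cfg$nonconversion_rate,
                                         cfg$nonconversion_alpha),
                    nrow(ds$mc), ncol(ds$mc))
  elig_gain <- eligible_sites(f1, site_anc, "gain")
  elig_loss <- eligible_sites(f1, site_anc, "loss")
  dev_gain <- compute_deviations(mc_gain, ds$tot, elig_gain, windows,
                                 "gain", ds$meta$individual)
  dev_loss <- compute_deviations(ds$mc, ds$tot, elig_loss, windows,
                                 "loss", ds$meta$individual)
  emit(rbind(dev_gain, dev_loss), "deviations.tsv")
  logf("deviations: %d gain cells, %d loss cells", nrow(dev_gain),
       nrow(dev_loss))

  # null-model variance check on a subsample of loss-eligible sites
  x_loss <- ifelse(elig_loss & ds$tot > 0, 1 - ds$mc / ds$tot, NA_real_)
  use_sites <- which(rowSums(!is.na(x_loss)) >= 2)
  if (length(use_sites) > cfg$n_null_sites) {
    use_sites <- sort(sample(use_sites, cfg$n_null_sites))
  }
  null_res <- NULL
  if (length(use_sites) >= 10) {
    xs <- x_loss[use_sites, , drop = FALSE]
    depths <- ds$tot[use_sites, , drop = FALSE]
    depths[is.na(xs)] <- 0L
    mr <- marginal_rates(xs)
    sims <- simulate_null(depths, mr, cfg$n_null_reps)
    null_res <- variance_comparison(xs, sims)
    jsonlite::write_json(null_res$summary,
                         file.path(out_dir, "nullmodel.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("nullmodel: above %.3f below %.3f",
         null_res$summary$above_frac, null_res$summary$below_frac)
  }

  # QTL scan on window phenotypes
  post <- array(0, c(nrow(ds$map), 3, nrow(ds$meta)))
  for (j in seq_len(nrow(ds$meta))) post[, , j] <- anc$paths[[j]]$posterior
  a_mat <- t(post[, 1, ] - post[, 3, ])
  d_mat <- t(post[, 2, ])
  qtl_res <- list()
  for (ty in c("gain", "loss")) {
    dev <- if (ty == "gain") dev_gain else dev_loss
    Y <- data.table::dcast(dev, individual ~ region,
                           value.var = "deviation")
    Y <- as.matrix(Y[match(ds$meta$individual, Y$individual), -1])
    keep <- colSums(!is.na(Y)) >= max(30L, nrow(Y) / 2)
    Y <- Y[, keep, drop = FALSE]
    if (ncol(Y) < 10L) next
    Y[is.na(Y)] <- matrix(colMeans(Y, na.rm = TRUE), nrow(Y), ncol(Y),
                          byrow = TRUE)[is.na(Y)]
    rot <- rotation_threshold(Y, a_mat, d_mat, ds$meta$temperature,
                              cfg$n_rotations, 0.99, cfg$seed)
    out <- data.table::data.table(marker = ds$map$marker,
                                  lod_sum = rot$observed$lod_sum,
                                  threshold = rot$threshold)
    emit(out, sprintf("qtl_%s.tsv", ty))
    qtl_res[[ty]] <- rot
    logf("qtl %s: max %.2f threshold %.2f", ty, rot$observed_max,
         rot$threshold)
  }

  # epimutation rates, grandparent vs F1, per lineage
  gain_mean <- rowSums(mc_gain * elig_gain) /
    pmax(rowSums(ds$tot * elig_gain), 1)
  loss_mean <- 1 - rowSums(ds$mc * elig_loss) /
    pmax(rowSums(ds$tot * elig_loss), 1)
  loss_mean[rowSums(ds$tot * elig_loss) == 0] <- NA_real_
  gain_mean[rowSums(ds$tot * elig_gain) == 0] <- NA_real_
  epi <- list()
  for (line in c("N", "S")) {
    gp <- if (line == "N") par_n$state else par_s$state
    f1s <- if (line == "N") f1$n_state else f1$s_state
    flt <- filter_stable_sites(gain_mean, loss_mean, gp, f1s,
                               cfg$gain_max, cfg$loss_max)
    epi[[line]] <- tryCatch(
      unclass(estimate_rates(gp, f1s, flt$retained, lineage = line)),
      error = function(e) list(lineage = line, error = conditionMessage(e)))
  }
  jsonlite::write_json(epi, file.path(out_dir, "epimutation.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("epimutation: N loss %.4g gain %.4g",
       epi$N$loss_rate %||% NA, epi$N$gain_rate %||% NA)

  invisible(list(dataset = ds, ancestry = anc, f1 = f1,
                 deviations = list(gain = dev_gain, loss = dev_loss),
                 nullmodel = null_res, qtl = qtl_res, epimutation = epi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(cfg) {
  # stable content hash without extra dependencies
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        seq_along(utf8ToInt(as.character(s)))) %% .Machine$integer.max)
}
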