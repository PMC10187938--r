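# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_sites = 2000L, n_f2 = 40L, n_parent_replicates = 3L,
         chrom_length_bp = 2000000L, marker_spacing_bp = 100000L,
         coverage_mean = 5, marker_coverage_mean = 2,
         gain_fold_pericentromere = 1, loss_fold_cgt = 1,
         gain_fold_nn_vs_ss = 1, loss_fold_ss_vs_nn = 1,
         gain_fold_differential = 1, loss_fold_differential = 1,
         epimutation_gain_rate = 0, epimutation_loss_rate = 0),
    list(...))
  do.call(sim_config, args)
}

# minimal F1 epigenotype table from explicit allele-state vectors
make_f1 <- function(n_state, s_state) {
  data.table::data.table(n_state = n_state, s_state = s_state,
                         class = classify_f1(n_state, s_state))
}

# methylome table from vectors (single chromosome, sorted positions)
make_methylome <- function(mc, total, chrom = "chr1",
                           pos = seq_along(mc) * 10L,
                           context = "CGA") {
  data.table::data.table(chrom = chrom, pos = pos, strand = "+",
                         context = context,
                         mc_count = as.integer(mc),
                         total_count = as.integer(total),
                         methylated_flag = as.integer(mc > 0))
}
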