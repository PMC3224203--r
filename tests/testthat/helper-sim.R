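# Shared small simulation configurations for the unit tests.

small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_blocks = 6, markers_per_block = 5,
                   n_haplotypes_pool = 100, within_block_recomb = 0.05,
                   n_cases = 120, n_controls = 180, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A tiny paired-record table with explicit values, for the concordance
# operations that do not need a simulation behind them.
manual_records <- function(p_emp, p_imp, maf_imp = NULL, chrom = NULL,
                           position = NULL) {
  n <- length(p_emp)
  df <- data.frame(
    chrom = if (is.null(chrom)) rep("1", n) else chrom,
    snp_id = sprintf("snp%03d", seq_len(n)),
    rsid = sprintf("rs%03d", seq_len(n)),
    position = if (is.null(position)) seq_len(n) * 1000L else position,
    allele_a = "A", allele_b = "G",
    p_emp = p_emp, p_imp = p_imp,
    stringsAsFactors = FALSE)
  df$maf_imp <- if (is.null(maf_imp)) rep(0.25, n) else maf_imp
  df$neglog_emp <- neglog10(p_emp)
  df$neglog_imp <- neglog10(p_imp)
  df$bias <- df$neglog_emp - df$neglog_imp
  df$status <- classify_marker(p_emp, p_imp, 1e-5)
  df
}
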