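# End-to-end orchestration: simulate -> associate -> QC -> compare ->
# LD blocks -> sliding windows, with TSV artifacts and a run manifest.

#' Run the full imputation-audit pipeline on a synthetic dataset
#'
#' Generates a paired dataset from `cfg`, runs the paired association scan,
#' applies the quality filters, classifies concordance, evaluates the LD
#' block summaries and builds the sliding windows. When `out_dir` is given,
#' the documented TSV artifacts and a JSON manifest are written there.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory; `NULL` keeps everything in
#'   memory.
#' @param alpha Headline significance threshold. Default `1e-5`.
#' @param model Headline inheritance model for the comparison.
#' @param filter A [filter_config()].
#' @param window_sizes Integer vector of window half-sizes. Default `1:3`.
#' @param ld_max_apart Marker-index cap for synthetic pairwise LD records.
#' @return A results bundle: list with `records` (kept, paired), `qc`,
#'   `concordance`, `sweep`, `top10`, `direction`, `block_summaries`,
#'   `ld_vs_bias`, `windows` (one element per k), `window_tests`, `sim`,
#'   `paths`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, alpha = 1e-5,
                         model = "logadd", filter = filter_config(),
                         window_sizes = 1:3, ld_max_apart = NULL) {
  sim <- simulate_paired_dataset(cfg)
  assoc <- run_association(sim$empiric, sim$imputed, sim$pheno)
  records_all <- pair_records(assoc, model = model, alpha = alpha)
  qc <- apply_filters(records_all, filter)
  records <- qc$kept

  conc <- concordance_table(records, alpha)
  sweep <- threshold_sweep(records, c(alpha, alpha / 10, alpha / 100))
  top10 <- top_k(records, min(10L, nrow(records)), arm = "imputed")
  direction <- effect_direction_summary(records, alpha)

  if (is.null(ld_max_apart)) ld_max_apart <- cfg$markers_per_block
  ld <- ld_from_haplotypes(sim$pool$haplotypes, sim$pool$markers,
                           max_apart = ld_max_apart)
  summaries <- block_summaries(build_blocks(ld, records$rsid))
  ld_vs_bias <- if (nrow(summaries) >= 3) {
    tryCatch(summary_vs_bias(records, summaries), error = function(e) NULL)
  } else NULL

  windows <- lapply(window_sizes, function(k) {
    build_windows(records, alpha = alpha, k = k)
  })
  names(windows) <- paste0("k", window_sizes)
  window_tests <- lapply(windows, function(w) {
    if (nrow(w) == 0) return(NULL)
    both <- length(unique(w$status)) == 2
    if (!both) return(NULL)
    lapply(c(sum = "sum", mean = "mean", variance = "variance"),
           function(s) compare_window_groups(w, s))
  })

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      results = file.path(out_dir, "results.tsv"),
      concordance = file.path(out_dir, "concordance.tsv"),
      sweep = file.path(out_dir, "threshold_sweep.tsv"),
      blocks = file.path(out_dir, "block_summaries.tsv"),
      windows = file.path(out_dir, "windows.tsv"),
      qc_report = file.path(out_dir, "qc_report.tsv"),
      manifest = file.path(out_dir, "manifest.json"))
    write_results(records[, names(results_schema())], paths$results)
    conc_df <- data.frame(
      cell = c("both_sig", "imp_only", "emp_only", "neither",
               "imp_sig_total", "emp_sig_total"),
      n = c(conc$n_both_sig, conc$n_imp_only, conc$n_emp_only,
            conc$n_neither, conc$n_imp_sig, conc$n_emp_sig))
    data.table::fwrite(conc_df, paths$concordance, sep = "\t")
    data.table::fwrite(sweep, paths$sweep, sep = "\t")
    data.table::fwrite(summaries, paths$blocks, sep = "\t")
    win_flat <- do.call(rbind, lapply(windows, function(w) {
      w$flank_values <- NULL
      w
    }))
    data.table::fwrite(win_flat, paths$windows, sep = "\t")
    data.table::fwrite(qc$report, paths$qc_report, sep = "\t")
    manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                     alpha = alpha, model = model,
                     n_markers_total = nrow(records_all),
                     n_markers_kept = nrow(records),
                     files = lapply(paths, basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  list(records = records, records_all = records_all, qc = qc,
       concordance = conc, sweep = sweep, top10 = top10,
       direction = direction, block_summaries = summaries,
       ld_vs_bias = ld_vs_bias, windows = windows,
       window_tests = window_tests, sim = sim, alpha = alpha,
       model = model, paths = paths)
}
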