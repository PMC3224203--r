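# Diagnostic graphics: paired scatter, QQ plots, genome tracks, predictor
# scans and window boxplots.

#' Scatterplot of paired -log10 p-values
#'
#' Empiric on the x axis, imputed on the y axis; points far above the
#' diagonal are markers whose imputed statistic overstates significance.
#'
#' @param records Paired-record table.
#' @return A ggplot object.
#' @export
plot_pair_scatter <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$neglog_emp, y = .data$neglog_imp)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::labs(x = expression(-log[10] * " p (empiric)"),
                  y = expression(-log[10] * " p (imputed)"))
}

#' QQ plot of one arm's p-values against the uniform null
#'
#' Expected order statistics of the uniform distribution on the -log10
#' scale.
#'
#' @param records Paired-record table.
#' @param arm `"empiric"` or `"imputed"`.
#' @return A ggplot object.
#' @export
plot_qq <- function(records, arm = c("empiric", "imputed")) {
  arm <- match.arg(arm)
  p <- sort(if (arm == "empiric") records$p_emp else records$p_imp)
  n <- length(p)
  df <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = neglog10(p)[order(-neglog10(p))])
  df$observed <- sort(neglog10(p), decreasing = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::labs(x = "expected -log10 p", y = paste0("observed (", arm, ")"))
}

#' Genome-ordered tracks of association and bias
#'
#' Markers are plotted against their rank in the (chromosome, position)
#' sort, chromosomes in alternating shades; panels show the empiric arm,
#' the imputed arm and the signed bias.
#'
#' @param records Paired-record table.
#' @return A ggplot object (facetted).
#' @export
plot_genome_tracks <- function(records) {
  ord <- order(chrom_key(records$chrom), records$position)
  rec <- records[ord, , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  rec$shade <- factor(chrom_key(rec$chrom) %% 2)
  long <- rbind(
    data.frame(rank = rec$rank, shade = rec$shade, panel = "empiric",
               value = rec$neglog_emp),
    data.frame(rank = rec$rank, shade = rec$shade, panel = "imputed",
               value = rec$neglog_imp),
    data.frame(rank = rec$rank, shade = rec$shade, panel = "bias",
               value = rec$bias))
  long$panel <- factor(long$panel, levels = c("empiric", "imputed", "bias"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value,
                                     colour = .data$shade)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey40", "black")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "marker rank (genome order)", y = NULL)
}

#' Scatter of a quality predictor against |bias|
#'
#' @param scan Output of [predictor_scan()].
#' @return A ggplot object.
#' @export
plot_predictor <- function(scan) {
  ggplot2::ggplot(scan$pairs,
                  ggplot2::aes(x = .data$predictor, y = .data$abs_bias)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = scan$which, y = "|bias|")
}

#' Boxplots of window summary statistics by center status
#'
#' @param windows Output of [build_windows()], possibly several k values
#'   row-bound.
#' @return A ggplot object.
#' @export
plot_window_boxplots <- function(windows) {
  long <- window_stats(windows)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$status, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$statistic),
                        cols = ggplot2::vars(.data$k), scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}

#' Render the diagnostic report for a pipeline bundle
#'
#' Saves the paired scatter (pre- and post-filter), per-arm QQ plots, the
#' genome tracks, the imputed-MAF predictor scan, window boxplots, and a
#' text summary with the threshold sweep, the concordance table and the
#' top-ranked imputed markers with their concordance labels.
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory for figures and `summary.txt`.
#' @return Invisibly, the vector of written file paths.
#' @export
render_report <- function(bundle, dir) {
  if (nrow(bundle$records) == 0) stop("empty results: nothing to render")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  save <- function(name, plot, width = 6, height = 5) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    path
  }
  files <- c(
    save("scatter_all.png", plot_pair_scatter(bundle$records_all)),
    save("scatter_filtered.png", plot_pair_scatter(bundle$records)),
    save("qq_empiric.png", plot_qq(bundle$records, "empiric")),
    save("qq_imputed.png", plot_qq(bundle$records, "imputed")),
    save("genome_tracks.png", plot_genome_tracks(bundle$records),
         width = 8, height = 6),
    save("predictor_maf.png",
         plot_predictor(predictor_scan(bundle$records, "maf_imp"))))
  win_all <- do.call(rbind, lapply(bundle$windows, function(w) {
    w$flank_values <- NULL
    w
  }))
  if (!is.null(win_all) && nrow(win_all) > 0) {
    files <- c(files, save("window_boxplots.png",
                           plot_window_boxplots(win_all),
                           width = 8, height = 6))
  }

  sum_path <- file.path(dir, "summary.txt")
  con <- file(sum_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("imputation audit summary (alpha = %g, model = %s)",
    bundle$alpha, bundle$model)
  w("markers analyzed: %d (kept after QC: %d)",
    nrow(bundle$records_all), nrow(bundle$records))
  w("")
  w("significant markers by threshold:")
  for (i in seq_len(nrow(bundle$sweep))) {
    w("  alpha %-8g empiric %5d  imputed %5d", bundle$sweep$alpha[i],
      bundle$sweep$n_emp_sig[i], bundle$sweep$n_imp_sig[i])
  }
  w("")
  cc <- bundle$concordance
  w("concordance: both=%d imp_only=%d emp_only=%d neither=%d",
    cc$n_both_sig, cc$n_imp_only, cc$n_emp_only, cc$n_neither)
  w("")
  w("top imputed markers:")
  t10 <- bundle$top10
  for (i in seq_len(nrow(t10))) {
    w("  %-10s chr%-3s %10d  p_emp=%.3g p_imp=%.3g  %s", t10$rsid[i],
      t10$chrom[i], t10$position[i], t10$p_emp[i], t10$p_imp[i],
      t10$concordance_label[i])
  }
  files <- c(files, sum_path)
  invisible(files)
}
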