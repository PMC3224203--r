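# Marker-level quality control.

#' Marker quality filter thresholds
#'
#' Defaults follow the standard GWAS practice the pipeline audits: calling
#' probability above 0.95 and MAF above 1%, applied jointly to both arms.
#' The HWE floor is disabled unless set.
#'
#' @param maf_min Minimum minor allele frequency (exclusive). Default 0.01.
#' @param call_min Minimum mean calling probability (exclusive).
#'   Default 0.95.
#' @param hwe_alpha Optional HWE p-value floor (inclusive); `NULL` disables
#'   the HWE criterion.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_min = 0.01, call_min = 0.95, hwe_alpha = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_min >= 0, call_min <= 1)
  if (!is.null(hwe_alpha)) stopifnot(hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(maf_min = maf_min, call_min = call_min,
                 hwe_alpha = hwe_alpha),
            class = "filter_config")
}

#' Apply marker-level quality filters
#'
#' A marker is kept only when BOTH arms pass every active criterion:
#' `maf > maf_min`, `call > call_min` and, when enabled,
#' `hwe >= hwe_alpha`. The exclusion report counts failures per criterion
#' (a marker failing several criteria counts under each).
#'
#' @param records Paired-record table carrying `maf_*`, `call_*`, `hwe_*`
#'   columns for both arms.
#' @param cfg A [filter_config()].
#' @return A list with `kept` (passing records), `excluded` (the rest),
#'   `report` (per-criterion failure counts plus the total) and `config`.
#' @export
apply_filters <- function(records, cfg = filter_config()) {
  need <- c("maf_emp", "maf_imp", "call_emp", "call_imp")
  if (!is.null(cfg$hwe_alpha)) need <- c(need, "hwe_emp", "hwe_imp")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fail_maf <- records$maf_emp <= cfg$maf_min | records$maf_imp <= cfg$maf_min
  fail_call <- records$call_emp <= cfg$call_min |
    records$call_imp <= cfg$call_min
  fail_hwe <- if (is.null(cfg$hwe_alpha)) rep(FALSE, nrow(records))
              else records$hwe_emp < cfg$hwe_alpha |
                records$hwe_imp < cfg$hwe_alpha
  keep <- !(fail_maf | fail_call | fail_hwe)
  report <- data.frame(
    criterion = c("maf", "call", "hwe", "total_excluded"),
    n_failed = c(sum(fail_maf), sum(fail_call), sum(fail_hwe), sum(!keep))
  )
  list(kept = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE],
       report = report, config = cfg)
}

#' Sweep quality thresholds and measure their effect
#'
#' For every combination of MAF and calling-probability thresholds,
#' recomputes the kept marker set, the Spearman correlation of the paired
#' -log10 p-values and the percentage of outliers among kept markers. An
#' outlier is a marker whose |bias| exceeds `outlier_bias` (default 2, i.e.
#' a 100-fold p-value disagreement).
#'
#' @param records Paired-record table.
#' @param maf_grid,call_grid Non-empty numeric threshold grids.
#' @param outlier_bias Absolute-bias cut defining an outlier.
#' @return A `data.frame` with one row per threshold combination:
#'   `maf_min`, `call_min`, `n_kept`, `spearman`, `outlier_pct`. Rows whose
#'   kept set is empty (or too small for a correlation) carry NAs and raise
#'   a warning.
#' @export
qc_sweep <- function(records, maf_grid, call_grid, outlier_bias = 2) {
  stopifnot(length(maf_grid) > 0, length(call_grid) > 0)
  grid <- expand.grid(maf_min = maf_grid, call_min = call_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- filter_config(maf_min = grid$maf_min[i],
                         call_min = grid$call_min[i])
    kept <- apply_filters(records, cfg)$kept
    n <- nrow(kept)
    if (n == 0) {
      warning(sprintf("empty kept set at maf_min=%g, call_min=%g",
                      cfg$maf_min, cfg$call_min))
      return(data.frame(maf_min = cfg$maf_min, call_min = cfg$call_min,
                        n_kept = 0L, spearman = NA_real_,
                        outlier_pct = NA_real_))
    }
    rho <- if (n < 3 || stats::sd(kept$neglog_emp) == 0 ||
               stats::sd(kept$neglog_imp) == 0) NA_real_
           else stats::cor(kept$neglog_emp, kept$neglog_imp,
                           method = "spearman")
    data.frame(maf_min = cfg$maf_min, call_min = cfg$call_min,
               n_kept = n, spearman = rho,
               outlier_pct = 100 * mean(abs(kept$bias) > outlier_bias))
  })
  do.call(rbind, rows)
}
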