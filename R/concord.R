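# Bias and concordance between empiric and imputed association statistics.

#' Minus-log10 transform of a p-value
#'
#' @param p Numeric vector of p-values in `[0, 1]`. Exact zeros (numeric
#'   underflow of extreme imputed p-values) are clipped to `1e-300` with a
#'   warning; values outside `[0, 1]` are an error.
#' @return `-log10(p)`, a non-negative vector.
#' @export
neglog10 <- function(p) {
  if (any(is.na(p))) stop("p-values must not be NA")
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]; offending value: ",
         p[which(p < 0 | p > 1)[1]])
  }
  if (any(p == 0)) {
    warning("p-value underflow: clipping 0 to 1e-300")
    p[p == 0] <- 1e-300
  }
  -log10(p)
}

#' Bias between paired association statistics
#'
#' The signed, scale-free disagreement between the two arms:
#' `(-log10 p_emp) - (-log10 p_imp)`. Negative values mean the imputed arm
#' claims more significance than direct genotyping supports.
#'
#' @param p_emp,p_imp P-values from the empiric and imputed arm.
#' @return Signed numeric vector.
#' @export
neglog_bias <- function(p_emp, p_imp) {
  neglog10(p_emp) - neglog10(p_imp)
}

#' Classify a marker's concordance at a significance threshold
#'
#' Significance is strict (`p < alpha`). The four-way status records which
#' arm(s), if any, call the marker associated.
#'
#' @param p_emp,p_imp P-values from the two arms (vectorized).
#' @param alpha Significance threshold in (0, 1).
#' @return Character vector with values `"concordant_sig"`,
#'   `"concordant_null"`, `"discordant_imp_only"`, `"discordant_emp_only"`.
#' @export
classify_marker <- function(p_emp, p_imp, alpha) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha < 1)
  se <- p_emp < alpha
  si <- p_imp < alpha
  ifelse(se & si, "concordant_sig",
         ifelse(!se & si, "discordant_imp_only",
                ifelse(se & !si, "discordant_emp_only", "concordant_null")))
}

#' Short concordance label for reporting
#'
#' Collapses the four-way status to the two-level vocabulary used in ranked
#' marker tables ("Concordant" / "Discordant").
#'
#' @param status Character vector of four-way statuses.
#' @return Character vector.
#' @export
status_label <- function(status) {
  ifelse(startsWith(status, "concordant"), "Concordant", "Discordant")
}

#' Build the paired-record table from an association scan
#'
#' Selects the headline model's p-values from a [run_association()] table
#' and appends the minus-log transforms, the bias and the concordance status
#' at `alpha`.
#'
#' @param assoc Output of [run_association()].
#' @param model Headline inheritance model; the log-additive (trend) model
#'   by default.
#' @param alpha Significance threshold used for the `status` column.
#' @return A paired-record `data.frame` following [results_schema()].
#' @export
pair_records <- function(assoc, model = c("logadd", "codominant", "dominant",
                                          "recessive"), alpha = 1e-5) {
  model <- match.arg(model)
  pcol <- paste0("p_", model)
  out <- assoc
  out$p_emp <- assoc[[paste0(pcol, "_emp")]]
  out$p_imp <- assoc[[paste0(pcol, "_imp")]]
  out$neglog_emp <- neglog10(out$p_emp)
  out$neglog_imp <- neglog10(out$p_imp)
  out$bias <- out$neglog_emp - out$neglog_imp
  out$status <- classify_marker(out$p_emp, out$p_imp, alpha)
  attr(out, "model") <- model
  attr(out, "alpha") <- alpha
  out
}

#' Concordance contingency table
#'
#' Cross-classifies markers by significance in each arm at `alpha` and
#' derives the per-arm significant totals.
#'
#' @param records Paired-record table (needs `p_emp`, `p_imp`).
#' @param alpha Significance threshold.
#' @return A `concordance_table` object (also buildable directly from cell
#'   counts with [concordance_cells()]).
#' @export
concordance_table <- function(records, alpha) {
  if (nrow(records) == 0) stop("records must be non-empty")
  status <- classify_marker(records$p_emp, records$p_imp, alpha)
  concordance_cells(
    n_both_sig = sum(status == "concordant_sig"),
    n_imp_only = sum(status == "discordant_imp_only"),
    n_emp_only = sum(status == "discordant_emp_only"),
    n_neither = sum(status == "concordant_null"),
    alpha = alpha
  )
}

#' @rdname concordance_table
#' @param n_both_sig,n_imp_only,n_emp_only,n_neither Non-negative cell
#'   counts of the 2x2 significance cross-classification.
#' @export
concordance_cells <- function(n_both_sig, n_imp_only, n_emp_only, n_neither,
                              alpha = NA_real_) {
  cells <- c(n_both_sig, n_imp_only, n_emp_only, n_neither)
  stopifnot(all(cells >= 0))
  structure(list(
    n_both_sig = n_both_sig, n_imp_only = n_imp_only,
    n_emp_only = n_emp_only, n_neither = n_neither,
    n_imp_sig = n_both_sig + n_imp_only,
    n_emp_sig = n_both_sig + n_emp_only,
    n_total = sum(cells), alpha = alpha
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("concordance at alpha = %s over %d markers\n",
              format(x$alpha), x$n_total))
  cat(sprintf("  both significant:     %d\n", x$n_both_sig))
  cat(sprintf("  imputed only:         %d\n", x$n_imp_only))
  cat(sprintf("  empiric only:         %d\n", x$n_emp_only))
  cat(sprintf("  neither:              %d\n", x$n_neither))
  cat(sprintf("  imputed significant:  %d\n", x$n_imp_sig))
  cat(sprintf("  empiric significant:  %d\n", x$n_emp_sig))
  invisible(x)
}

#' Per-threshold significant-marker counts
#'
#' @param records Paired-record table.
#' @param alphas Numeric vector of thresholds; processed in descending
#'   order.
#' @return A `data.frame` with columns `alpha`, `n_emp_sig`, `n_imp_sig`.
#' @export
threshold_sweep <- function(records, alphas) {
  alphas <- sort(alphas, decreasing = TRUE)
  data.frame(
    alpha = alphas,
    n_emp_sig = vapply(alphas, function(a) sum(records$p_emp < a), numeric(1)),
    n_imp_sig = vapply(alphas, function(a) sum(records$p_imp < a), numeric(1))
  )
}

#' Spearman rank correlation of the paired -log10 p-values
#'
#' @param records Paired-record table (needs `neglog_emp`, `neglog_imp`);
#'   at least 3 rows, neither vector constant.
#' @return Spearman coefficient in `[-1, 1]` (average-rank tie handling).
#' @export
rank_correlation <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records")
  x <- records$neglog_emp; y <- records$neglog_imp
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined: constant -log10 p vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Top-k markers by one arm's p-values
#'
#' @param records Paired-record table.
#' @param k Number of markers to return.
#' @param arm Which arm's p-value ranks the markers.
#' @return The `k` records with smallest p in the chosen arm, ties broken by
#'   (chromosome, position), with a `concordance_label` column appended.
#' @export
top_k <- function(records, k, arm = c("imputed", "empiric")) {
  arm <- match.arg(arm)
  stopifnot(k >= 1)
  if (k > nrow(records)) {
    warning("k exceeds record count; returning all records")
    k <- nrow(records)
  }
  p <- if (arm == "imputed") records$p_imp else records$p_emp
  ord <- order(p, chrom_key(records$chrom), records$position)
  out <- records[ord[seq_len(k)], , drop = FALSE]
  out$concordance_label <- status_label(out$status)
  rownames(out) <- NULL
  out
}

#' Effect directions and magnitudes of false-positive imputed markers
#'
#' Summarizes the imputed-arm odds ratios of the markers significant by the
#' imputed arm only: counts of protective vs susceptibility minor-allele
#' effects (null directions excluded from both counts) and the median /
#' min / max of the coined odds ratio.
#'
#' @param records Paired-record table.
#' @param alpha Significance threshold for the classification.
#' @return A list with `n`, `n_protective`, `n_susceptibility`,
#'   `median_or_coined`, `min_or_coined`, `max_or_coined`, `empty`.
#' @export
effect_direction_summary <- function(records, alpha) {
  status <- classify_marker(records$p_emp, records$p_imp, alpha)
  fp <- records[status == "discordant_imp_only", , drop = FALSE]
  if (nrow(fp) == 0) {
    return(list(n = 0L, n_protective = 0L, n_susceptibility = 0L,
                median_or_coined = NA_real_, min_or_coined = NA_real_,
                max_or_coined = NA_real_, empty = TRUE))
  }
  list(
    n = nrow(fp),
    n_protective = sum(fp$direction_imp == "protective"),
    n_susceptibility = sum(fp$direction_imp == "susceptibility"),
    median_or_coined = stats::median(fp$or_coined_imp),
    min_or_coined = min(fp$or_coined_imp),
    max_or_coined = max(fp$or_coined_imp),
    empty = FALSE
  )
}

# Decile bins of a predictor with the median |bias| per bin.
decile_bins <- function(predictor, abs_bias) {
  qs <- unique(stats::quantile(predictor, probs = seq(0, 1, 0.1),
                               names = FALSE))
  if (length(qs) < 2) {
    return(data.frame(decile = 1L, lo = qs, hi = qs,
                      n = length(predictor),
                      median_abs_bias = stats::median(abs_bias)))
  }
  bin <- cut(predictor, breaks = qs, include.lowest = TRUE, labels = FALSE)
  agg <- lapply(sort(unique(bin)), function(b) {
    data.frame(decile = b, lo = qs[b], hi = qs[b + 1],
               n = sum(bin == b),
               median_abs_bias = stats::median(abs_bias[bin == b]))
  })
  do.call(rbind, agg)
}

#' Scan a quality metric as a predictor of |bias|
#'
#' For one marker-level predictor (imputed MAF, either arm's calling
#' quality, or HWE p-value) returns the scatter-ready (predictor, |bias|)
#' pairs, their Spearman correlation and decile-binned median |bias|.
#'
#' @param records Paired-record table with at least 3 rows.
#' @param predictor One of `"maf_imp"`, `"call_emp"`, `"call_imp"`,
#'   `"hwe_emp"`, `"hwe_imp"`.
#' @return A list with `pairs` (data.frame `predictor`, `abs_bias`), `rho`
#'   (NA when the predictor is constant) and `bins`.
#' @export
predictor_scan <- function(records, predictor = c("maf_imp", "call_emp",
                                                  "call_imp", "hwe_emp",
                                                  "hwe_imp")) {
  predictor <- match.arg(predictor)
  if (nrow(records) < 3) stop("need at least 3 records")
  x <- records[[predictor]]
  ab <- abs(records$bias)
  rho <- if (stats::sd(x) == 0 || stats::sd(ab) == 0) NA_real_
         else stats::cor(x, ab, method = "spearman")
  list(pairs = data.frame(predictor = x, abs_bias = ab),
       rho = rho, bins = decile_bins(x, ab), which = predictor)
}

#' Markers at extreme minor allele frequencies
#'
#' Partitions records by the imputed-arm MAF into a rare subset
#' (`maf < lo`) and a near-0.5 subset (`maf > hi`); boundary values fall in
#' neither (strict inequalities). Also reports each subset's concordance
#' fraction at `alpha`.
#'
#' @param records Paired-record table.
#' @param lo,hi MAF cut points; defaults 0.01 and 0.49.
#' @param alpha Significance threshold for the concordance fractions.
#' @return A list with `low`, `high` (record subsets) and `concordance`
#'   (data.frame `subset`, `n`, `frac_concordant`).
#' @export
extreme_maf_subset <- function(records, lo = 0.01, hi = 0.49, alpha = 1e-5) {
  low <- records[records$maf_imp < lo, , drop = FALSE]
  high <- records[records$maf_imp > hi, , drop = FALSE]
  frac <- function(df) {
    if (nrow(df) == 0) return(NA_real_)
    mean(startsWith(classify_marker(df$p_emp, df$p_imp, alpha), "concordant"))
  }
  list(low = low, high = high,
       concordance = data.frame(
         subset = c("low", "high"),
         n = c(nrow(low), nrow(high)),
         frac_concordant = c(frac(low), frac(high))))
}
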