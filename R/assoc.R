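# Association statistics from posterior-expected genotype counts.
#
# All tests consume a case/control x {AA, AB, BB} table of possibly
# fractional counts: summing posterior triplets within each phenotype
# stratum realizes, in expectation, a meta-population that respects the
# observed or imputed genotype frequencies. Hard calls are the special case
# of one-hot triplets. Genotypes are coded as the count of allele B.

#' Construct a case/control genotype count table
#'
#' @param case,control Numeric length-3 vectors of (nAA, nAB, nBB) counts;
#'   fractional values are allowed (posterior-expected counts).
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(case, control) {
  case <- as.numeric(case); control <- as.numeric(control)
  if (length(case) != 3 || length(control) != 3) {
    stop("case and control must each hold 3 genotype counts")
  }
  if (any(case < 0) || any(control < 0)) stop("counts must be non-negative")
  if (sum(case) <= 0 || sum(control) <= 0) {
    stop("empty stratum: each of case and control must have positive total")
  }
  structure(list(case = setNames(case, c("AA", "AB", "BB")),
                 control = setNames(control, c("AA", "AB", "BB"))),
            class = "genotype_counts")
}

#' Posterior-expected genotype counts for one SNP
#'
#' Sums genotype-probability triplets within the case and control strata,
#' producing the (possibly fractional) expected count table every
#' association test consumes.
#'
#' @param probs Numeric matrix with one row per individual and columns
#'   (pAA, pAB, pBB).
#' @param status Integer vector, 0 = control and 1 = case, one entry per
#'   individual.
#' @return A [genotype_counts()] object.
#' @export
expected_counts <- function(probs, status) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 3) stop("probs must have 3 columns (pAA, pAB, pBB)")
  if (nrow(probs) != length(status)) {
    stop("status length must match the number of individuals")
  }
  status <- as.integer(status)
  if (sum(status == 1) == 0 || sum(status == 0) == 0) {
    stop("empty stratum: need at least one case and one control")
  }
  genotype_counts(colSums(probs[status == 1, , drop = FALSE]),
                  colSums(probs[status == 0, , drop = FALSE]))
}

# ---- vectorized kernels: M x 3 count matrices for cases and controls ----

# Pooled allele-B frequency; maf = min(f, 1 - f).
maf_vec <- function(case, control) {
  pooled <- case + control
  n <- rowSums(pooled)
  f <- (pooled[, 2] + 2 * pooled[, 3]) / (2 * n)
  pmin(f, 1 - f)
}

# Pearson chi-square on the full 2x3 table, df = polymorphic columns - 1.
codominant_vec <- function(case, control) {
  r <- rowSums(case); s <- rowSums(control)
  colsum <- case + control
  n <- r + s
  ec <- colsum * (r / n)
  es <- colsum * (s / n)
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  stat <- rowSums(term(case, ec)) + rowSums(term(control, es))
  df <- pmax(rowSums(colsum > 0) - 1L, 0L)
  p <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)
  list(statistic = stat, df = df, p = p,
       flag = rep(FALSE, length(stat)))
}

# 2x2 Pearson chi-square with Haldane-Anscombe 0.5 on zero margins.
chisq_2x2_vec <- function(a, b, c, d) {
  zero <- (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, df = rep(1L, length(stat)),
       p = stats::pchisq(stat, 1, lower.tail = FALSE), flag = zero)
}

# Dominant/recessive collapse with respect to allele B:
# dominant: {AA} vs {AB, BB}; recessive: {AA, AB} vs {BB}.
dominant_vec <- function(case, control) {
  chisq_2x2_vec(case[, 1], case[, 2] + case[, 3],
                control[, 1], control[, 2] + control[, 3])
}

recessive_vec <- function(case, control) {
  chisq_2x2_vec(case[, 1] + case[, 2], case[, 3],
                control[, 1] + control[, 2], control[, 3])
}

# Cochran-Armitage trend test with scores (0, 1, 2); the score-test
# equivalent of the one-degree-of-freedom additive logistic model.
trend_vec <- function(case, control) {
  s <- c(0, 1, 2)
  r_tot <- rowSums(case)
  n_tot <- rowSums(case) + rowSums(control)
  totals <- case + control
  sum_sr <- as.vector(case %*% s)
  sum_sn <- as.vector(totals %*% s)
  sum_s2n <- as.vector(totals %*% s^2)
  num <- (n_tot * sum_sr - r_tot * sum_sn)^2 * n_tot
  den <- r_tot * (n_tot - r_tot) * (n_tot * sum_s2n - sum_sn^2)
  stat <- ifelse(den > 0, num / den, 0)
  p <- ifelse(den > 0, stats::pchisq(stat, 1, lower.tail = FALSE), 1)
  list(statistic = stat, df = rep(1L, length(stat)), p = p,
       flag = rep(FALSE, length(stat)))
}

# Hardy-Weinberg 1-df goodness of fit on pooled, integer-rounded counts.
hwe_vec <- function(case, control) {
  pooled <- round(case + control)
  n <- rowSums(pooled)
  f <- ifelse(n > 0, (pooled[, 2] + 2 * pooled[, 3]) / (2 * n), 0)
  e <- cbind(n * (1 - f)^2, n * 2 * f * (1 - f), n * f^2)
  term <- ifelse(e > 0, (pooled - e)^2 / e, 0)
  stat <- rowSums(term)
  mono <- f <= 0 | f >= 1 | n == 0
  p <- ifelse(mono, 1, stats::pchisq(stat, 1, lower.tail = FALSE))
  list(statistic = ifelse(mono, 0, stat), p = p)
}

# Allelic odds ratio with the minor allele as exposure; 0.5 added to every
# cell of the allele-count 2x2 when any cell is zero (flagged).
or_vec <- function(case, control) {
  case_b <- case[, 2] + 2 * case[, 3]
  case_a <- 2 * case[, 1] + case[, 2]
  ctrl_b <- control[, 2] + 2 * control[, 3]
  ctrl_a <- 2 * control[, 1] + control[, 2]
  f_b <- (case_b + ctrl_b) / (case_a + case_b + ctrl_a + ctrl_b)
  minor_is_b <- f_b <= 0.5
  a <- ifelse(minor_is_b, case_b, case_a)   # case, minor allele
  b <- ifelse(minor_is_b, case_a, case_b)   # case, major allele
  cc <- ifelse(minor_is_b, ctrl_b, ctrl_a)  # control, minor
  dd <- ifelse(minor_is_b, ctrl_a, ctrl_b)  # control, major
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  cc <- cc + 0.5 * zero; dd <- dd + 0.5 * zero
  or <- (a * dd) / (b * cc)
  direction <- ifelse(or > 1, "susceptibility",
                      ifelse(or < 1, "protective", "null"))
  list(or = or, or_coined = pmax(or, 1 / or), direction = direction,
       flag = zero)
}

# ---- scalar interfaces over single count tables ----

as_count_rows <- function(t) {
  stopifnot(inherits(t, "genotype_counts"))
  list(case = matrix(t$case, nrow = 1), control = matrix(t$control, nrow = 1))
}

#' Minor allele frequency from a genotype count table
#'
#' Pooled over cases and controls: the allele-B frequency is
#' `(nAB + 2 nBB) / (2 N)`; the MAF is the smaller of it and its complement.
#'
#' @param t A [genotype_counts()] object.
#' @return MAF in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(t) {
  r <- as_count_rows(t)
  maf_vec(r$case, r$control)
}

#' Per-SNP calling quality
#'
#' Mean over individuals of the maximum posterior probability; 1 for hard
#' calls and 1/3 for completely uninformative triplets.
#'
#' @param probs Numeric matrix, one row per individual, columns
#'   (pAA, pAB, pBB).
#' @return A value in `[1/3, 1]`.
#' @export
call_quality <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1) stop("need at least one individual")
  mean(pmax(probs[, 1], probs[, 2], probs[, 3]))
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of the pooled
#' (cases + controls, rounded to integers) genotype counts against the
#' p^2 / 2pq / q^2 expectations. Monomorphic markers return p = 1 by
#' convention.
#'
#' @param t A [genotype_counts()] object.
#' @return A list with `statistic` and `p`.
#' @export
hwe_test <- function(t) {
  r <- as_count_rows(t)
  res <- hwe_vec(r$case, r$control)
  list(statistic = res$statistic[1], p = res$p[1])
}

#' Association test of one marker under a genetic model
#'
#' Codominant: Pearson chi-square on the 2x3 table (2 df). Dominant /
#' recessive: genotypes collapsed to 2x2 with respect to allele B
#' (`{AA}` vs `{AB,BB}`, and `{AA,AB}` vs `{BB}`). Log-additive:
#' Cochran-Armitage trend test with scores (0, 1, 2), 1 df. Fractional
#' counts are used as-is. A zero margin in a collapsed 2x2 triggers the
#' Haldane-Anscombe 0.5 continuity addition and sets the `flag`.
#'
#' @param t A [genotype_counts()] object.
#' @param model One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"logadditive"`.
#' @return A list with `statistic`, `df`, `p` and logical `flag`.
#' @export
model_test <- function(t, model = c("codominant", "dominant", "recessive",
                                    "logadditive")) {
  model <- match.arg(model)
  r <- as_count_rows(t)
  res <- switch(model,
    codominant = codominant_vec(r$case, r$control),
    dominant = dominant_vec(r$case, r$control),
    recessive = recessive_vec(r$case, r$control),
    logadditive = trend_vec(r$case, r$control))
  lapply(res, `[`, 1)
}

#' Allelic odds ratio of one marker
#'
#' Cross-product ratio on the allele-count 2x2 with the minor allele as
#' exposure. The coined odds ratio is `max(OR, 1/OR)`; the direction labels
#' the minor allele as susceptibility (OR > 1), protective (OR < 1) or null.
#' A zero allele-count cell triggers the 0.5 continuity addition (flagged).
#'
#' @param t A [genotype_counts()] object.
#' @return A list with `or`, `or_coined`, `direction`, `flag`.
#' @export
allelic_odds_ratio <- function(t) {
  r <- as_count_rows(t)
  res <- or_vec(r$case, r$control)
  lapply(res, `[`, 1)
}

# Case/control expected-count matrices for every marker of a posterior
# matrix at once (columns of the posterior matrices are individuals).
count_matrices <- function(pm, status) {
  stopifnot(inherits(pm, "posterior_matrix"))
  status <- as.numeric(status)
  if (length(status) != n_individuals(pm)) {
    stop("phenotype length must match the number of individuals")
  }
  if (sum(status == 1) == 0 || sum(status == 0) == 0) {
    stop("empty stratum: need at least one case and one control")
  }
  case <- cbind(pm$p_aa %*% status, pm$p_ab %*% status, pm$p_bb %*% status)
  ctrl <- cbind(pm$p_aa %*% (1 - status), pm$p_ab %*% (1 - status),
                pm$p_bb %*% (1 - status))
  list(case = case, control = ctrl)
}

# Full per-arm summary for every marker: all four model p-values, MAF,
# calling quality, HWE p, odds ratio.
arm_summary <- function(pm, status) {
  cm <- count_matrices(pm, status)
  cod <- codominant_vec(cm$case, cm$control)
  dom <- dominant_vec(cm$case, cm$control)
  rec <- recessive_vec(cm$case, cm$control)
  tre <- trend_vec(cm$case, cm$control)
  hwe <- hwe_vec(cm$case, cm$control)
  or <- or_vec(cm$case, cm$control)
  data.frame(
    maf = maf_vec(cm$case, cm$control),
    call = rowMeans(pmax(pm$p_aa, pm$p_ab, pm$p_bb)),
    hwe = hwe$p,
    p_codominant = cod$p, p_dominant = dom$p, p_recessive = rec$p,
    p_logadd = tre$p,
    or = or$or, or_coined = or$or_coined, direction = or$direction,
    cc_flag = dom$flag | rec$flag | or$flag,
    stringsAsFactors = FALSE
  )
}

#' Paired empiric/imputed association scan
#'
#' Runs the full per-marker association summary on both arms over the
#' intersection of their marker sets, keyed by rsid. Markers present in only
#' one arm are excluded and counted in the `dropped` attribute.
#'
#' @param empiric,imputed [posterior_matrix()] objects sharing (part of)
#'   their marker set.
#' @param pheno Phenotype `data.frame` with columns `id` and `status`
#'   (0 = control, 1 = case), or a bare 0/1 vector. When both the phenotype
#'   and the posterior matrices carry identifiers, individuals are aligned
#'   by id.
#' @return A `data.frame` with one row per shared marker, holding marker
#'   identity plus every per-arm statistic with `_emp` / `_imp` suffixes.
#'   Attribute `dropped` counts markers excluded from each arm.
#' @export
run_association <- function(empiric, imputed, pheno) {
  stopifnot(inherits(empiric, "posterior_matrix"),
            inherits(imputed, "posterior_matrix"))
  if (is.data.frame(pheno)) {
    status <- pheno$status
    ids <- pheno$id
  } else {
    status <- pheno
    ids <- NULL
  }
  align <- function(pm) {
    if (!is.null(ids) && !is.null(pm$sample_ids)) {
      idx <- match(ids, pm$sample_ids)
      if (anyNA(idx)) stop("phenotype ids missing from posterior matrix")
      pm$p_aa <- pm$p_aa[, idx, drop = FALSE]
      pm$p_ab <- pm$p_ab[, idx, drop = FALSE]
      pm$p_bb <- pm$p_bb[, idx, drop = FALSE]
      pm$sample_ids <- ids
    }
    pm
  }
  empiric <- align(empiric); imputed <- align(imputed)

  shared <- intersect(empiric$markers$rsid, imputed$markers$rsid)
  if (length(shared) == 0) stop("no shared markers between the two arms")
  dropped <- c(empiric = n_markers(empiric) - length(shared),
               imputed = n_markers(imputed) - length(shared))
  e_idx <- match(shared, empiric$markers$rsid)
  i_idx <- match(shared, imputed$markers$rsid)
  emp <- reorder_posterior(empiric, e_idx)
  imp <- reorder_posterior(imputed, i_idx)
  ord <- order(chrom_key(emp$markers$chrom), emp$markers$position)
  emp <- reorder_posterior(emp, ord)
  imp <- reorder_posterior(imp, ord)

  se <- arm_summary(emp, status)
  si <- arm_summary(imp, status)
  names(se) <- paste0(names(se), "_emp")
  names(si) <- paste0(names(si), "_imp")
  out <- cbind(emp$markers, se, si)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
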