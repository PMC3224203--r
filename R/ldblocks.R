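# Marker-centric haplotypic blocks from pairwise r2 measures.
#
# A block, in this pipeline's sense, is not a partitioned interval: it is
# the complete multiset of pairwise r2 values involving a given marker,
# with no distance cap or minimum-r2 threshold. The four summary statistics
# (mean, median, max, variance) characterize the local LD consistency that
# imputation leans on.

#' Pairwise r-squared between two loci from phased haplotypes
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = hAB - pA pB` estimated from
#' haplotype frequencies.
#'
#' @param hap_a,hap_b Binary (0/1) haplotype vectors of equal length >= 2;
#'   both loci must be polymorphic.
#' @return r-squared in `[0, 1]`.
#' @export
r2_pairwise <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b) || length(hap_a) < 2) {
    stop("haplotype vectors must have equal length >= 2")
  }
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1))) {
    stop("haplotype vectors must be binary 0/1")
  }
  pa <- mean(hap_a); pb <- mean(hap_b)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1) {
    stop("r2 undefined for a monomorphic locus")
  }
  d <- mean(hap_a * hap_b) - pa * pb
  min(1, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Pairwise LD records computed from a haplotype matrix
#'
#' Builds a HapMap-style LD record table (pos1, pos2, rsids, D', r2) from
#' phased haplotypes, restricted to same-chromosome pairs at most
#' `max_apart` markers from each other. This stands in for a downloaded LD
#' table when the haplotypes are simulated.
#'
#' @param haplotypes Binary matrix, haplotypes in rows and markers in
#'   columns.
#' @param markers Marker table aligned with the columns.
#' @param max_apart Maximum marker-index distance between pair members.
#' @param population Label stored in the population column.
#' @return An LD `data.frame` in the [read_ld_table()] layout. Monomorphic
#'   pairs are skipped.
#' @export
ld_from_haplotypes <- function(haplotypes, markers, max_apart = 10L,
                               population = "SIM") {
  stopifnot(ncol(haplotypes) == nrow(markers))
  m <- ncol(haplotypes)
  p <- colMeans(haplotypes)
  poly <- p > 0 & p < 1
  out <- vector("list", max_apart)
  for (d in seq_len(min(max_apart, m - 1))) {
    i <- seq_len(m - d); j <- i + d
    ok <- poly[i] & poly[j] & markers$chrom[i] == markers$chrom[j]
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    p12 <- colMeans(haplotypes[, i, drop = FALSE] *
                    haplotypes[, j, drop = FALSE])
    dd <- p12 - p[i] * p[j]
    r2 <- dd^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    dmax <- ifelse(dd >= 0, pmin(p[i] * (1 - p[j]), (1 - p[i]) * p[j]),
                   pmin(p[i] * p[j], (1 - p[i]) * (1 - p[j])))
    out[[d]] <- data.frame(
      pos1 = markers$position[i], pos2 = markers$position[j],
      population = population,
      rsid1 = markers$rsid[i], rsid2 = markers$rsid[j],
      dprime = ifelse(dmax > 0, pmin(1, abs(dd) / dmax), 0),
      r2 = pmin(1, r2), lod = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      population = character(0), rsid1 = character(0),
                      rsid2 = character(0), dprime = numeric(0),
                      r2 = numeric(0), lod = numeric(0)))
  }
  do.call(rbind, out)
}

#' Build per-marker haplotypic blocks from LD records
#'
#' Every LD record contributes its r2 value to the blocks of BOTH endpoint
#' markers; duplicate records are retained (blocks are multisets). Markers
#' named in `marker_ids` but absent from every record are reported as
#' blockless.
#'
#' @param ld LD record `data.frame` as from [read_ld_table()] or
#'   [ld_from_haplotypes()].
#' @param marker_ids Optional character vector of markers of interest.
#' @return A list with `blocks` (named list, marker id -> numeric vector of
#'   r2 values) and `blockless` (character vector).
#' @export
build_blocks <- function(ld, marker_ids = NULL) {
  ids <- c(ld$rsid1, ld$rsid2)
  vals <- c(ld$r2, ld$r2)
  blocks <- split(vals, ids)
  if (is.null(marker_ids)) {
    blockless <- character(0)
  } else {
    blockless <- setdiff(marker_ids, names(blocks))
  }
  list(blocks = blocks, blockless = blockless)
}

#' Summary statistics of one haplotypic block
#'
#' Mean, median, maximum and population variance (divide by n; 0 for a
#' single-pair block) of the block's r2 values.
#'
#' @param block Numeric vector of r2 values, length >= 1.
#' @return A one-row `data.frame`: `n_pairs`, `mean_r2`, `median_r2`,
#'   `max_r2`, `var_r2`.
#' @export
block_summary <- function(block) {
  if (length(block) < 1) stop("empty block")
  n <- length(block)
  data.frame(n_pairs = n, mean_r2 = mean(block),
             median_r2 = stats::median(block), max_r2 = max(block),
             var_r2 = sum((block - mean(block))^2) / n)
}

#' Summaries for every block of a block list
#'
#' @param blocks Output of [build_blocks()] (or its `blocks` element).
#' @return A `data.frame` with one row per marker: `marker` plus the
#'   [block_summary()] columns.
#' @export
block_summaries <- function(blocks) {
  if (!is.null(blocks$blocks)) blocks <- blocks$blocks
  if (length(blocks) == 0) {
    return(data.frame(marker = character(0), n_pairs = integer(0),
                      mean_r2 = numeric(0), median_r2 = numeric(0),
                      max_r2 = numeric(0), var_r2 = numeric(0)))
  }
  out <- do.call(rbind, lapply(blocks, block_summary))
  out <- cbind(data.frame(marker = names(blocks), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Block summary statistics as predictors of |bias|
#'
#' Joins the paired records with the block summaries on marker id and
#' evaluates each of the four r2 summaries as a predictor of the absolute
#' bias: Spearman correlation plus decile-binned median |bias|.
#'
#' @param records Paired-record table (needs `rsid` and `bias`).
#' @param summaries Output of [block_summaries()].
#' @return A named list (mean_r2, median_r2, max_r2, var_r2) of lists with
#'   `rho` and `bins`, plus element `n_shared`.
#' @export
summary_vs_bias <- function(records, summaries) {
  merged <- merge(records[, c("rsid", "bias")], summaries,
                  by.x = "rsid", by.y = "marker")
  if (nrow(merged) < 3) stop("need at least 3 markers shared with summaries")
  ab <- abs(merged$bias)
  one <- function(col) {
    x <- merged[[col]]
    rho <- if (stats::sd(x) == 0 || stats::sd(ab) == 0) NA_real_
           else stats::cor(x, ab, method = "spearman")
    list(rho = rho, bins = decile_bins(x, ab))
  }
  out <- lapply(c(mean_r2 = "mean_r2", median_r2 = "median_r2",
                  max_r2 = "max_r2", var_r2 = "var_r2"), one)
  out$n_shared <- nrow(merged)
  out
}
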