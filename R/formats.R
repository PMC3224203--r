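# File formats: Oxford GEN/SAMPLE, HapMap pairwise-LD tables, results TSV.

#' Construct a marker information table
#'
#' A marker table holds the identity and genomic coordinates of biallelic
#' autosomal SNPs: chromosome label, platform identifier, dbSNP identifier,
#' 1-based base-pair position and the two alleles.
#'
#' @param chrom Character vector of chromosome labels (autosomes `"1"`..`"22"`).
#' @param snp_id Character vector of platform marker identifiers.
#' @param rsid Character vector of dbSNP identifiers.
#' @param position Integer vector of 1-based base-pair coordinates.
#' @param allele_a,allele_b Single-character alleles (A/C/G/T); must differ
#'   within a marker.
#' @return A `data.frame` with columns `chrom`, `snp_id`, `rsid`, `position`,
#'   `allele_a`, `allele_b`.
#' @export
marker_info <- function(chrom, snp_id, rsid, position, allele_a, allele_b) {
  df <- data.frame(
    chrom = as.character(chrom), snp_id = as.character(snp_id),
    rsid = as.character(rsid), position = as.integer(position),
    allele_a = as.character(allele_a), allele_b = as.character(allele_b),
    stringsAsFactors = FALSE
  )
  validate_marker_info(df)
  df
}

validate_marker_info <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "snp_id", "rsid", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("marker table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$position)) || any(df$position <= 0)) {
    stop("marker positions must be positive integers")
  }
  bad_allele <- !(df$allele_a %in% c("A", "C", "G", "T")) |
    !(df$allele_b %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) {
    stop("alleles must be single characters A/C/G/T (marker ",
         df$rsid[which(bad_allele)[1]], ")")
  }
  if (any(df$allele_a == df$allele_b)) {
    stop("allele_a and allele_b must differ (marker ",
         df$rsid[which(df$allele_a == df$allele_b)[1]], ")")
  }
  invisible(df)
}

# Numeric chromosome key for sorting ("1".."22"; anything else sorts last).
chrom_key <- function(chrom) {
  k <- suppressWarnings(as.integer(chrom))
  k[is.na(k)] <- .Machine$integer.max
  k
}

#' Construct a posterior genotype-probability matrix
#'
#' Per-marker, per-individual genotype probability triplets
#' (pAA, pAB, pBB), the common carrier for both directly genotyped markers
#' (one-hot triplets) and imputed markers (soft posteriors). Triplets whose
#' sum deviates from 1 by at most `tol_hard` are renormalized; larger
#' deviations are rejected.
#'
#' @param markers Marker table as from [marker_info()], one row per marker.
#' @param p_aa,p_ab,p_bb Numeric matrices, markers in rows and individuals in
#'   columns, holding the probability of each genotype.
#' @param sample_ids Optional character vector of individual identifiers.
#' @param tol_renorm Deviations up to this value are renormalized silently
#'   (GEN files round probabilities to 3-4 decimals). Default `1e-4`.
#' @param tol_hard Deviations above this value are an error. Default `1e-2`.
#' @return An object of class `posterior_matrix`: a list with elements
#'   `markers`, `p_aa`, `p_ab`, `p_bb`, `sample_ids`.
#' @export
posterior_matrix <- function(markers, p_aa, p_ab, p_bb, sample_ids = NULL,
                             tol_renorm = 1e-4, tol_hard = 1e-2) {
  validate_marker_info(markers)
  p_aa <- as.matrix(p_aa); p_ab <- as.matrix(p_ab); p_bb <- as.matrix(p_bb)
  if (!all(dim(p_aa) == dim(p_ab)) || !all(dim(p_aa) == dim(p_bb))) {
    stop("probability matrices must share dimensions")
  }
  if (nrow(p_aa) != nrow(markers)) {
    stop("probability matrices must have one row per marker")
  }
  if (!is.null(sample_ids) && length(sample_ids) != ncol(p_aa)) {
    stop("sample_ids length must equal the number of individuals")
  }
  if (any(p_aa < 0) || any(p_ab < 0) || any(p_bb < 0)) {
    stop("genotype probabilities must be non-negative")
  }
  s <- p_aa + p_ab + p_bb
  dev <- abs(s - 1)
  if (any(dev > tol_hard)) {
    bad <- which(dev > tol_hard, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "triplet sum %.4f deviates from 1 beyond %.0e (marker %s, individual %d)",
      s[bad[1], bad[2]], tol_hard, markers$rsid[bad[1]], bad[2]))
  }
  if (any(dev > tol_renorm)) {
    warning("some triplet sums deviate from 1 by more than ", tol_renorm,
            "; renormalizing")
  }
  if (any(dev > 0)) {
    p_aa <- p_aa / s; p_ab <- p_ab / s; p_bb <- p_bb / s
  }
  structure(
    list(markers = markers, p_aa = p_aa, p_ab = p_ab, p_bb = p_bb,
         sample_ids = sample_ids),
    class = "posterior_matrix"
  )
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("posterior_matrix: %d markers x %d individuals\n",
              nrow(x$p_aa), ncol(x$p_aa)))
  invisible(x)
}

#' Number of markers / individuals in a posterior matrix
#' @param x A `posterior_matrix`.
#' @return Integer count.
#' @export
n_markers <- function(x) nrow(x$p_aa)

#' @rdname n_markers
#' @export
n_individuals <- function(x) ncol(x$p_aa)

# Reorder the rows of a posterior matrix.
reorder_posterior <- function(x, idx) {
  posterior_matrix(x$markers[idx, , drop = FALSE],
                   x$p_aa[idx, , drop = FALSE],
                   x$p_ab[idx, , drop = FALSE],
                   x$p_bb[idx, , drop = FALSE],
                   sample_ids = x$sample_ids)
}

#' Read an Oxford GEN genotype-probability file
#'
#' Parses the space-delimited GEN dialect family: each line carries 5
#' (`snp_id rsid position alleleA alleleB`) or 6 (leading chromosome column)
#' metadata fields followed by 3 probability fields per individual. The
#' dialect is auto-detected from the field count and metadata content of the
#' first line. Markers are sorted by (chromosome, position) after loading;
#' individual order is never changed.
#'
#' @param path Path to a `.gen` file.
#' @param chrom Chromosome label to use for every marker when the file has no
#'   leading chromosome column. Default `"0"`.
#' @return A [posterior_matrix()].
#' @export
read_gen <- function(path, chrom = "0") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(posterior_matrix(
      marker_info(character(0), character(0), character(0), integer(0),
                  character(0), character(0)),
      matrix(0, 0, 0), matrix(0, 0, 0), matrix(0, 0, 0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)

  looks_like <- function(f, meta) {
    # metadata plausibility: position numeric and positive, alleles ACGT
    if (length(f) < meta + 3) return(FALSE)
    if ((length(f) - meta) %% 3 != 0) return(FALSE)
    pos_idx <- if (meta == 6) 4L else 3L
    pos <- suppressWarnings(as.numeric(f[pos_idx]))
    if (is.na(pos) || pos <= 0) return(FALSE)
    all(f[(pos_idx + 1):(pos_idx + 2)] %in% c("A", "C", "G", "T"))
  }
  meta <- if (looks_like(fields[[1]], 6L)) 6L
          else if (looks_like(fields[[1]], 5L)) 5L
          else stop("parse error at line 1: cannot detect GEN dialect ",
                    "(field count ", nf[1], " fits neither 5- nor 6-column ",
                    "metadata plus whole triplets)")
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop(sprintf("parse error at line %d: %d fields, expected %d",
                 bad[1], nf[bad[1]], nf[1]))
  }
  n_ind <- (nf[1] - meta) / 3L

  mat <- do.call(rbind, fields)
  if (meta == 6L) {
    mk <- data.frame(chrom = mat[, 1], snp_id = mat[, 2], rsid = mat[, 3],
                     position = suppressWarnings(as.integer(mat[, 4])),
                     allele_a = mat[, 5], allele_b = mat[, 6],
                     stringsAsFactors = FALSE)
  } else {
    mk <- data.frame(chrom = chrom, snp_id = mat[, 1], rsid = mat[, 2],
                     position = suppressWarnings(as.integer(mat[, 3])),
                     allele_a = mat[, 4], allele_b = mat[, 5],
                     stringsAsFactors = FALSE)
  }
  probs <- suppressWarnings(
    matrix(as.numeric(mat[, (meta + 1):nf[1], drop = FALSE]),
           nrow = length(lines)))
  if (anyNA(probs)) {
    bad <- which(apply(is.na(probs), 1, any))[1]
    stop("parse error at line ", bad, ": non-numeric probability field")
  }
  sel <- function(g) probs[, seq(g, by = 3, length.out = n_ind), drop = FALSE]
  pm <- posterior_matrix(mk, sel(1), sel(2), sel(3))
  ord <- order(chrom_key(pm$markers$chrom), pm$markers$position)
  reorder_posterior(pm, ord)
}

#' Write an Oxford GEN genotype-probability file
#'
#' Always emits the 6-column dialect (leading chromosome), probabilities with
#' four decimal places.
#'
#' @param data A [posterior_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gen <- function(data, path) {
  stopifnot(inherits(data, "posterior_matrix"))
  m <- n_markers(data)
  if (m == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  n <- n_individuals(data)
  meta <- with(data$markers,
               paste(chrom, snp_id, rsid, position, allele_a, allele_b))
  if (n > 0) {
    fmt <- function(x) formatC(x, format = "f", digits = 4)
    full <- matrix("", nrow = m, ncol = 3L * n)
    full[, seq(1L, 3L * n, by = 3L)] <- fmt(data$p_aa)
    full[, seq(2L, 3L * n, by = 3L)] <- fmt(data$p_ab)
    full[, seq(3L, 3L * n, by = 3L)] <- fmt(data$p_bb)
    probs <- do.call(paste, as.data.frame(full, stringsAsFactors = FALSE))
    meta <- paste(meta, probs)
  }
  writeLines(meta, path)
  invisible(path)
}

#' Read an Oxford SAMPLE phenotype file
#'
#' Expects the standard layout: a header row, a column-type row (e.g.
#' `0 0 0 B`), then one row per individual whose last column is the binary
#' case/control phenotype (0 = control, 1 = case). The first column is taken
#' as the individual identifier.
#'
#' @param path Path to a `.sample` file.
#' @return A `data.frame` with columns `id` (character) and `status`
#'   (integer 0/1).
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("empty cohort: SAMPLE file has no individuals")
  rows <- strsplit(trimws(lines), "[ \t]+")
  body <- rows[-(1:2)]
  id <- vapply(body, `[`, character(1), 1L)
  ph_chr <- vapply(body, function(r) r[length(r)], character(1))
  if (any(ph_chr %in% c("NA", "-9", ""))) {
    stop("missing phenotype for individual ",
         id[which(ph_chr %in% c("NA", "-9", ""))[1]])
  }
  ph <- suppressWarnings(as.numeric(ph_chr))
  if (anyNA(ph) || !all(ph %in% c(0, 1))) {
    stop("phenotype must be binary 0/1; offending value: ",
         ph_chr[which(is.na(ph) | !(ph %in% c(0, 1)))[1]])
  }
  out <- data.frame(id = id, status = as.integer(ph), stringsAsFactors = FALSE)
  if (sum(out$status == 1) == 0 || sum(out$status == 0) == 0) {
    stop("cohort must contain at least one case and one control")
  }
  out
}

#' Write an Oxford SAMPLE phenotype file
#'
#' @param pheno A `data.frame` with columns `id` and `status` (0/1).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(pheno, path) {
  stopifnot(is.data.frame(pheno), all(c("id", "status") %in% names(pheno)))
  lines <- c("ID_1 ID_2 missing pheno", "0 0 0 B",
             paste(pheno$id, pheno$id, 0, pheno$status))
  writeLines(lines, path)
  invisible(path)
}

#' Read a HapMap-style pairwise-LD table
#'
#' Whitespace-delimited columns
#' `pos1 pos2 population rsid1 rsid2 Dprime R2 LOD` (the `ld_chrN.txt`
#' dialect). The population column is preserved but unused downstream.
#'
#' @param path Path to the LD text file.
#' @return A `data.frame` with columns `pos1`, `pos2`, `population`, `rsid1`,
#'   `rsid2`, `dprime`, `r2`, `lod`. Empty file gives zero rows.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      population = character(0), rsid1 = character(0),
                      rsid2 = character(0), dprime = numeric(0),
                      r2 = numeric(0), lod = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1)) == 0) return(empty)
  df <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          colClasses = list(character = c(3, 4, 5)))
  if (ncol(df) != 8) stop("LD table must have 8 columns, found ", ncol(df))
  names(df) <- c("pos1", "pos2", "population", "rsid1", "rsid2",
                 "dprime", "r2", "lod")
  if (any(df$r2 < 0 | df$r2 > 1)) {
    stop("r2 outside [0,1] at row ", which(df$r2 < 0 | df$r2 > 1)[1])
  }
  if (any(df$dprime < 0 | df$dprime > 1)) {
    stop("Dprime outside [0,1] at row ",
         which(df$dprime < 0 | df$dprime > 1)[1])
  }
  if (any(df$pos1 >= df$pos2)) {
    stop("pos1 must be smaller than pos2 at row ",
         which(df$pos1 >= df$pos2)[1])
  }
  df$pos1 <- as.integer(df$pos1); df$pos2 <- as.integer(df$pos2)
  df
}

#' Column vocabulary of the paired-results TSV
#'
#' @return Named character vector mapping column name to storage type.
#' @export
results_schema <- function() {
  c(chrom = "character", snp_id = "character", rsid = "character",
    position = "integer", allele_a = "character", allele_b = "character",
    maf_emp = "double", maf_imp = "double",
    call_emp = "double", call_imp = "double",
    hwe_emp = "double", hwe_imp = "double",
    p_codominant_emp = "double", p_dominant_emp = "double",
    p_recessive_emp = "double", p_logadd_emp = "double",
    p_codominant_imp = "double", p_dominant_imp = "double",
    p_recessive_imp = "double", p_logadd_imp = "double",
    or_emp = "double", or_imp = "double",
    or_coined_emp = "double", or_coined_imp = "double",
    direction_emp = "character", direction_imp = "character",
    cc_flag_emp = "logical", cc_flag_imp = "logical",
    p_emp = "double", p_imp = "double",
    neglog_emp = "double", neglog_imp = "double",
    bias = "double", status = "character")
}

#' Write / read the pipeline's paired-results TSV
#'
#' Tab-separated, one header row. P-value columns are serialized in
#' scientific notation with full double precision (17 significant digits, so
#' at least the six the format guarantees) and all other doubles with enough
#' digits to round-trip exactly. `read_results` rejects files carrying
#' columns outside the documented vocabulary.
#'
#' @param records A paired-results `data.frame` whose columns belong to the
#'   documented schema (see [results_schema()]).
#' @param path File path.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   the records `data.frame`.
#' @export
write_results <- function(records, path) {
  schema <- results_schema()
  unknown <- setdiff(names(records), names(schema))
  if (length(unknown) > 0) {
    stop("unknown results column(s): ", paste(unknown, collapse = ", "))
  }
  out <- records
  for (nm in names(out)) {
    if (schema[[nm]] == "double") {
      fmt <- if (startsWith(nm, "p_")) "%.16e" else "%.17g"
      out[[nm]] <- ifelse(is.na(records[[nm]]), "NA",
                          sprintf(fmt, records[[nm]]))
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- results_schema()
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  unknown <- setdiff(hdr, names(schema))
  if (length(unknown) > 0) {
    stop("unknown results column(s): ", paste(unknown, collapse = ", "))
  }
  classes <- as.list(schema[hdr])
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = unlist(classes), na.strings = "NA")
  df
}
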