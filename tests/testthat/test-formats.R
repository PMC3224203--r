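# Oxford GEN/SAMPLE, LD-table and results-TSV I/O.

random_gen_pm <- function(m = 8, n = 5, seed = 11) {
  set.seed(seed)
  mk <- marker_info(chrom = rep("2", m), snp_id = sprintf("snp%d", 1:m),
                    rsid = sprintf("rs%d", 1:m),
                    position = sort(sample.int(1e6, m)),
                    allele_a = "A", allele_b = "G")
  # probabilities on a 1e-4 grid so the 4-decimal GEN format is lossless
  p_aa <- matrix(0, m, n); p_ab <- matrix(0, m, n); p_bb <- matrix(0, m, n)
  for (j in 1:n) {
    tr <- t(stats::rmultinom(m, 10000, c(2, 3, 1)) / 10000)
    p_aa[, j] <- tr[, 1]; p_ab[, j] <- tr[, 2]; p_bb[, j] <- tr[, 3]
  }
  posterior_matrix(mk, p_aa, p_ab, p_bb)
}

test_that("read_gen parses the 6-column dialect and certain homozygotes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines("1 snp1 rs1 1000 A G 1 0 0", f)
  pm <- read_gen(f)
  expect_equal(pm$markers$rsid, "rs1")
  expect_equal(pm$markers$chrom, "1")
  expect_equal(pm$markers$position, 1000L)
  expect_equal(c(pm$p_aa[1, 1], pm$p_ab[1, 1], pm$p_bb[1, 1]), c(1, 0, 0))
})

test_that("read_gen parses the 5-column dialect with a supplied chromosome", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines("snp1 rs1 1000 A G 0.25 0.5 0.25", f)
  pm <- read_gen(f, chrom = "7")
  expect_equal(pm$markers$chrom, "7")
  expect_equal(pm$p_ab[1, 1], 0.5)
})

test_that("GEN write/read round-trips and formats with 4 decimals", {
  pm <- random_gen_pm()
  f <- withr::local_tempfile(fileext = ".gen")
  write_gen(pm, f)
  line1 <- readLines(f, n = 1)
  expect_match(line1, "\\d\\.\\d{4}( |$)")
  back <- read_gen(f)
  expect_equal(back$markers, pm$markers)
  expect_equal(back$p_aa, pm$p_aa, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$p_ab, pm$p_ab, tolerance = 1e-12, ignore_attr = TRUE)
  # one specific triplet formatting check
  f2 <- withr::local_tempfile(fileext = ".gen")
  mk <- pm$markers[1, , drop = FALSE]
  one <- posterior_matrix(mk, matrix(0.25), matrix(0.5), matrix(0.25))
  write_gen(one, f2)
  expect_match(readLines(f2), "0.2500 0.5000 0.2500", fixed = TRUE)
})

test_that("write_gen on an empty marker set yields an empty file", {
  pm <- posterior_matrix(
    marker_info(character(0), character(0), character(0), integer(0),
                character(0), character(0)),
    matrix(0, 0, 0), matrix(0, 0, 0), matrix(0, 0, 0))
  f <- withr::local_tempfile(fileext = ".gen")
  write_gen(pm, f)
  expect_length(readLines(f), 0)
})

test_that("malformed GEN lines are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".gen")
  # 8 probability fields cannot be whole triplets under either dialect
  writeLines("1 snp1 rs1 1000 A G 1 0 0 1 0 0 0.2 0.8", f)
  expect_error(read_gen(f), "line 1")
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("1 snp1 rs1 1000 A G 1 0 0",
               "1 snp2 rs2 2000 A G 1 0"), f2)
  expect_error(read_gen(f2), "line 2")
})

test_that("triplet sums beyond the hard tolerance are a validation error", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines("1 snp1 rs1 1000 A G 0.5 0.5 0.5", f)
  expect_error(read_gen(f), "deviates")
  # within the soft tolerance, triplets are renormalized
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines("1 snp1 rs1 1000 A G 0.3334 0.3333 0.3333", f2)
  pm <- read_gen(f2)
  expect_equal(pm$p_aa[1, 1] + pm$p_ab[1, 1] + pm$p_bb[1, 1], 1)
})

test_that("markers come out (chrom, position)-sorted; individuals untouched", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("10 snpA rsA 500 A G 0 1 0 1 0 0",
               "2 snpB rsB 900 C T 1 0 0 0 0 1",
               "2 snpC rsC 100 A C 0 0 1 0 1 0"), f)
  pm <- read_gen(f)
  expect_equal(pm$markers$rsid, c("rsC", "rsB", "rsA"))
  # rsC row kept its per-individual order
  expect_equal(pm$p_bb[1, ], c(1, 0))
})

test_that("SAMPLE files round-trip and reject bad phenotypes", {
  ph <- data.frame(id = c("a", "b", "c"), status = c(1L, 0L, 0L))
  f <- withr::local_tempfile(fileext = ".sample")
  write_sample(ph, f)
  back <- read_sample(f)
  expect_equal(back$status, c(1L, 0L, 0L))
  expect_equal(sum(back$status == 1), 1)

  f2 <- withr::local_tempfile(fileext = ".sample")
  writeLines(c("ID_1 ID_2 missing pheno", "0 0 0 B", "x x 0 2"), f2)
  expect_error(read_sample(f2), "binary")

  f3 <- withr::local_tempfile(fileext = ".sample")
  writeLines(c("ID_1 ID_2 missing pheno", "0 0 0 B"), f3)
  expect_error(read_sample(f3), "empty cohort")

  f4 <- withr::local_tempfile(fileext = ".sample")
  writeLines(c("ID_1 ID_2 missing pheno", "0 0 0 B", "x x 0 NA"), f4)
  expect_error(read_sample(f4), "missing phenotype")
})

test_that("LD tables parse, validate ranges and accept empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("1000 2000 CEU rs1 rs2 1.0 1.0 10.1", f)
  ld <- read_ld_table(f)
  expect_equal(ld$r2, 1.0)
  expect_equal(ld$rsid2, "rs2")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1000 2000 CEU rs1 rs2 1.0 1.7 10.1", f2)
  expect_error(read_ld_table(f2), "r2")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f3)
  expect_equal(nrow(read_ld_table(f3)), 0)
})

test_that("results TSV round-trips losslessly, including extreme p-values", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_paired_dataset(cfg)
  assoc <- run_association(sim$empiric, sim$imputed, sim$pheno)
  rec <- pair_records(assoc)[1:3, ]
  rec$p_imp[1] <- 1.57e-30
  rec$neglog_imp <- neglog10(rec$p_imp)
  rec$bias <- rec$neglog_emp - rec$neglog_imp
  rec <- rec[, names(results_schema())]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(rec, f)
  back <- read_results(f)
  expect_equal(back, rec, tolerance = 0, ignore_attr = TRUE)
  expect_identical(back$p_imp[1], 1.57e-30)
  expect_true(all(back$status %in% c("concordant_sig", "concordant_null",
                                     "discordant_imp_only",
                                     "discordant_emp_only")))
})

test_that("read_results rejects unknown columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tmystery", "rs1\t1"), f)
  expect_error(read_results(f), "unknown results column")
})
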