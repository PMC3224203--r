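# Bias, classification, concordance tables and predictor scans.

test_that("neglog10 transforms, clips underflow and rejects bad input", {
  expect_equal(neglog10(c(1, 0.1, 1e-5)), c(0, 1, 5))
  expect_warning(v <- neglog10(0), "underflow")
  expect_equal(v, 300)
  expect_error(neglog10(-0.1), "\\[0, 1\\]")
  expect_error(neglog10(1.5), "\\[0, 1\\]")
  expect_error(neglog10(NA_real_), "NA")
})

test_that("bias reproduces the hand-worked example", {
  # p_emp = 1e-3, p_imp = 5.61e-14: bias = 3 - 13.251 = -10.251
  expect_equal(neglog_bias(1e-3, 5.61e-14), -10.251, tolerance = 1e-3)
  expect_equal(neglog_bias(0.01, 0.01), 0)
})

test_that("classification is strict at the threshold and vectorized", {
  expect_equal(classify_marker(1e-6, 1e-6, 1e-5), "concordant_sig")
  expect_equal(classify_marker(1e-5, 1e-6, 1e-5), "discordant_imp_only")
  expect_equal(classify_marker(1e-6, 1e-5, 1e-5), "discordant_emp_only")
  # exactly alpha is NOT significant
  expect_equal(classify_marker(1e-5, 1e-5, 1e-5), "concordant_null")
  expect_equal(
    classify_marker(c(1e-6, 0.5), c(0.5, 1e-6), 1e-5),
    c("discordant_emp_only", "discordant_imp_only"))
  expect_error(classify_marker(0.5, 0.5, 0), "alpha")
  expect_equal(status_label(c("concordant_sig", "discordant_imp_only",
                              "concordant_null")),
               c("Concordant", "Discordant", "Concordant"))
})

test_that("concordance table cells add up and derive per-arm totals", {
  ct <- concordance_cells(38, 35, 0, 317182, alpha = 1e-5)
  expect_equal(ct$n_imp_sig, 73)
  expect_equal(ct$n_emp_sig, 38)
  expect_equal(ct$n_total, 317255)
  expect_output(print(ct), "imputed only:\\s+35")

  rec <- manual_records(p_emp = c(1e-8, 1e-3, 0.5, 1e-7),
                        p_imp = c(1e-9, 1e-8, 0.4, 1e-3))
  ct2 <- concordance_table(rec, 1e-5)
  expect_equal(ct2$n_both_sig, 1)
  expect_equal(ct2$n_imp_only, 1)
  expect_equal(ct2$n_emp_only, 1)
  expect_equal(ct2$n_neither, 1)
  expect_error(concordance_table(rec[0, ], 1e-5), "non-empty")
})

test_that("threshold sweep counts per arm in descending alpha order", {
  hits <- t2d_top_hits()
  rec <- data.frame(p_emp = hits$p_empiric, p_imp = hits$p_imputed)
  sw <- threshold_sweep(rec, c(1e-12, 1e-5))
  expect_equal(sw$alpha, c(1e-5, 1e-12))
  expect_equal(sw$n_emp_sig, c(1, 1))
  expect_equal(sw$n_imp_sig, c(10, 9))
})

test_that("rank correlation matches the rank-vector oracle", {
  rec <- manual_records(p_emp = 10^-c(1, 2, 3, 4),
                        p_imp = 10^-c(1, 3, 2, 4))
  expect_equal(rank_correlation(rec), 0.8, tolerance = 1e-12)
  expect_equal(rank_correlation(rec),
               oracle_spearman(rec$neglog_emp, rec$neglog_imp),
               tolerance = 1e-12)

  # invariance under strictly monotone transformation of one arm
  set.seed(2)
  p1 <- stats::runif(50); p2 <- stats::runif(50)
  ra <- manual_records(p1, p2)
  rb <- manual_records(p1^3, p2)
  expect_equal(rank_correlation(ra), rank_correlation(rb), tolerance = 1e-12)

  expect_error(rank_correlation(ra[1:2, ]), "at least 3")
  expect_error(rank_correlation(manual_records(rep(0.5, 5),
                                               stats::runif(5))), "constant")
})

test_that("top_k ranks by the chosen arm with positional tie-breaking", {
  rec <- manual_records(p_emp = c(0.5, 0.5, 0.5, 0.5),
                        p_imp = c(1e-3, 1e-6, 1e-6, 1e-2),
                        chrom = c("2", "10", "2", "1"),
                        position = c(100L, 100L, 900L, 100L))
  top <- top_k(rec, 2, arm = "imputed")
  # tied at 1e-6: chromosome 2 sorts before chromosome 10 numerically
  expect_equal(top$rsid, c("rs003", "rs002"))
  expect_equal(top$concordance_label, c("Discordant", "Discordant"))

  top_e <- top_k(rec, 1, arm = "empiric")
  expect_equal(top_e$chrom, "1")  # all tied; smallest (chrom, position)

  expect_warning(all4 <- top_k(rec, 10), "exceeds")
  expect_equal(nrow(all4), 4)
})

test_that("effect direction summary counts and coins odds ratios", {
  rec <- manual_records(p_emp = rep(0.5, 4),
                        p_imp = c(1e-8, 1e-9, 1e-7, 0.9))
  rec$direction_imp <- c("protective", "protective", "susceptibility", "null")
  rec$or_coined_imp <- c(1.25, 1.11, 1.50, 1.00)
  s <- effect_direction_summary(rec, 1e-5)
  expect_equal(s$n, 3)
  expect_equal(s$n_protective, 2)
  expect_equal(s$n_susceptibility, 1)
  expect_equal(s$median_or_coined, 1.25)
  expect_equal(s$max_or_coined, 1.50)
  expect_false(s$empty)

  s0 <- effect_direction_summary(rec[4, , drop = FALSE], 1e-5)
  expect_true(s0$empty)
  expect_true(is.na(s0$median_or_coined))
})

test_that("predictor scan computes rho and decile medians of |bias|", {
  set.seed(7)
  n <- 200
  maf <- stats::runif(n, 0.01, 0.5)
  # |bias| grows with MAF by construction -> positive rho, top decile max
  p_emp <- rep(0.01, n)
  p_imp <- 10^-(2 + maf * 10 + stats::runif(n, 0, 0.1))
  rec <- manual_records(p_emp, p_imp, maf_imp = maf)
  sc <- predictor_scan(rec, "maf_imp")
  expect_gt(sc$rho, 0.9)
  expect_equal(sc$rho, oracle_spearman(maf, abs(rec$bias)), tolerance = 1e-12)
  expect_equal(nrow(sc$bins), 10)
  expect_equal(which.max(sc$bins$median_abs_bias), 10L)
  expect_equal(sum(sc$bins$n), n)

  # constant predictor -> rho NA but bins still defined
  rec2 <- manual_records(p_emp[1:5], p_imp[1:5], maf_imp = rep(0.3, 5))
  sc2 <- predictor_scan(rec2, "maf_imp")
  expect_true(is.na(sc2$rho))
  expect_error(predictor_scan(rec[1:2, ], "maf_imp"), "at least 3")
  expect_error(predictor_scan(rec, "nonsense"))
})

test_that("extreme MAF subsets use strict cut points", {
  rec <- manual_records(p_emp = rep(0.5, 5), p_imp = c(0.5, 1e-8, 0.5, 0.5, 0.5),
                        maf_imp = c(0.005, 0.495, 0.01, 0.49, 0.25))
  ex <- extreme_maf_subset(rec, lo = 0.01, hi = 0.49, alpha = 1e-5)
  expect_equal(ex$low$rsid, "rs001")
  expect_equal(ex$high$rsid, "rs002")
  expect_equal(ex$concordance$n, c(1, 1))
  expect_equal(ex$concordance$frac_concordant, c(1, 0))

  ex2 <- extreme_maf_subset(rec[5, , drop = FALSE])
  expect_true(all(is.na(ex2$concordance$frac_concordant)))
})
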