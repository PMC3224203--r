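# Synthetic paired-dataset generator.

test_that("derived seeds are deterministic, distinct and in range", {
  expect_equal(derive_seed(42, 101), derive_seed(42, 101))
  expect_false(derive_seed(42, 101) == derive_seed(42, 202))
  expect_false(derive_seed(42, 101) == derive_seed(43, 101))
  s <- vapply(1:50, function(i) derive_seed(i, 101), integer(1))
  expect_true(all(s >= 0 & s < 2147483647))
})

test_that("zero recombination copies whole blocks; 0.5 decouples markers", {
  cfg0 <- small_cfg(seed = 8, n_blocks = 3, markers_per_block = 4,
                    within_block_recomb = 0, maf_range = c(0.3, 0.5),
                    n_haplotypes_pool = 200)
  pool0 <- simulate_haplotype_pool(cfg0)
  for (b in 1:3) {
    cols <- which(pool0$block_id == b)
    for (j in cols[-1]) {
      expect_equal(pool0$haplotypes[, j], pool0$haplotypes[, cols[1]])
    }
  }
  expect_true(all(pool0$mean_block_r2 == 1))

  cfg5 <- small_cfg(seed = 8, n_blocks = 3, markers_per_block = 4,
                    within_block_recomb = 0.5, maf_range = c(0.3, 0.5),
                    n_haplotypes_pool = 400)
  pool5 <- simulate_haplotype_pool(cfg5)
  # independent markers: mean pairwise r2 is near 1/pool-size
  expect_lt(mean(pool5$mean_block_r2), 0.05)
})

test_that("per-block recombination vectors are honored", {
  cfg <- small_cfg(seed = 3, n_blocks = 2, markers_per_block = 5,
                   within_block_recomb = c(0, 0.5),
                   maf_range = c(0.3, 0.5), n_haplotypes_pool = 300)
  pool <- simulate_haplotype_pool(cfg)
  r2_b1 <- mean(pool$mean_block_r2[pool$block_id == 1])
  r2_b2 <- mean(pool$mean_block_r2[pool$block_id == 2])
  expect_equal(r2_b1, 1)
  expect_lt(r2_b2, 0.1)
  expect_error(small_cfg(within_block_recomb = c(0, 0.5, 0.1)),
               "per block")
})

test_that("pool markers carry a sorted, block-consistent map", {
  cfg <- small_cfg(seed = 2)
  pool <- simulate_haplotype_pool(cfg)
  mk <- pool$markers
  expect_equal(nrow(mk), 30)
  expect_false(is.unsorted(order(chrom_key(mk$chrom), mk$position)))
  # within a block: same chromosome, 4 kb spacing
  cols <- which(pool$block_id == 1)
  expect_length(unique(mk$chrom[cols]), 1)
  expect_equal(unique(diff(mk$position[cols])), 4000L)
})

test_that("cohort reaches the requested sizes with cases first", {
  cfg <- small_cfg(seed = 4)
  pool <- simulate_haplotype_pool(cfg)
  cohort <- simulate_cohort(pool, cfg)
  expect_equal(sum(cohort$pheno$status == 1), 120)
  expect_equal(sum(cohort$pheno$status == 0), 180)
  expect_equal(cohort$pheno$status, rep(c(1L, 0L), c(120, 180)))
  expect_equal(dim(cohort$truth$calls), c(30, 300))
  expect_true(all(cohort$truth$calls %in% 0:2))
})

test_that("the logistic disease model recovers the causal odds ratio", {
  cfg <- small_cfg(seed = 17, n_blocks = 8, markers_per_block = 4,
                   n_haplotypes_pool = 400, n_cases = 1000,
                   n_controls = 1500,
                   causal = data.frame(block = 2, marker = 2, or = 1.5))
  pool <- simulate_haplotype_pool(cfg)
  cohort <- simulate_cohort(pool, cfg)
  idx <- (2 - 1) * 4 + 2
  g <- cohort$truth$calls[idx, ]
  fit <- stats::glm(cohort$pheno$status ~ g, family = stats::binomial())
  beta_hat <- unname(stats::coef(fit)["g"])
  # the estimate should sit within ~3 standard errors of log(1.5)
  se <- sqrt(diag(stats::vcov(fit)))["g"]
  expect_lt(abs(beta_hat - log(1.5)), 3 * se + 0.05)
})

test_that("missing calls become uninformative empiric triplets", {
  cfg <- small_cfg(seed = 6, missing_rate = 0.1)
  sim <- simulate_paired_dataset(cfg)
  na_frac <- mean(is.na(sim$truth$calls))
  expect_gt(na_frac, 0.05); expect_lt(na_frac, 0.15)
  i <- which(is.na(sim$truth$calls))[1]
  expect_equal(sim$empiric$p_aa[i], 1 / 3)
  expect_equal(sim$empiric$p_ab[i], 1 / 3)
})

test_that("the error-free channel reproduces the empiric arm exactly", {
  cfg <- small_cfg(seed = 5, error = error_config(uncertainty_level = 0))
  sim <- simulate_paired_dataset(cfg)
  expect_equal(sim$imputed$p_aa, sim$empiric$p_aa, ignore_attr = TRUE)
  expect_equal(sim$imputed$p_bb, sim$empiric$p_bb, ignore_attr = TRUE)
  expect_length(attr(sim$imputed, "flipped"), 0)
  expect_length(attr(sim$imputed, "noised"), 0)
})

test_that("full uncertainty collapses every triplet to 1/3", {
  cfg <- small_cfg(seed = 5, error = error_config(uncertainty_level = 1))
  sim <- simulate_paired_dataset(cfg)
  expect_true(all(abs(sim$imputed$p_aa - 1 / 3) < 1e-12))
  expect_true(all(abs(sim$imputed$p_ab - 1 / 3) < 1e-12))
})

test_that("the default uncertainty yields the conventional call quality", {
  cfg <- small_cfg(seed = 5)  # uncertainty_level 0.075
  sim <- simulate_paired_dataset(cfg)
  probs <- cbind(as.vector(sim$imputed$p_aa), as.vector(sim$imputed$p_ab),
                 as.vector(sim$imputed$p_bb))
  expect_equal(call_quality(probs), 0.95, tolerance = 1e-12)
})

test_that("non-differential label flips leave the pooled MAF invariant", {
  cfg <- small_cfg(seed = 9,
                   error = error_config(uncertainty_level = 0,
                                        flip_rsids = c("rs000001",
                                                       "rs000007")))
  sim <- simulate_paired_dataset(cfg)
  expect_setequal(attr(sim$imputed, "flipped"), c("rs000001", "rs000007"))
  res <- run_association(sim$empiric, sim$imputed, sim$pheno)
  expect_equal(res$maf_emp, res$maf_imp, tolerance = 1e-12)
  # and the association statistic is flip-invariant too
  expect_equal(res$p_logadd_emp, res$p_logadd_imp, tolerance = 1e-10)
})

test_that("differential flips at near-0.5 MAF create imputed-only signal", {
  flips <- sprintf("rs%06d", c(3, 8, 13, 18, 23))
  cfg <- small_cfg(seed = 10, maf_range = c(0.4, 0.5),
                   n_cases = 400, n_controls = 600,
                   error = error_config(uncertainty_level = 0,
                                        flip_rsids = flips,
                                        differential = TRUE))
  sim <- simulate_paired_dataset(cfg)
  res <- run_association(sim$empiric, sim$imputed, sim$pheno)
  rec <- pair_records(res, alpha = 1e-5)
  hit <- rec$rsid %in% flips
  # flipped markers: imputed arm far more significant than empiric
  expect_true(all(rec$bias[hit] < 0))
  expect_gt(median(rec$neglog_imp[hit]), 5)
  # untouched markers stay concordant
  expect_equal(rec$p_emp[!hit], rec$p_imp[!hit], tolerance = 1e-10)
})

test_that("low-LD noise targets only weak-LD blocks", {
  cfg <- small_cfg(seed = 12, n_blocks = 4, markers_per_block = 5,
                   within_block_recomb = c(0.01, 0.01, 0.45, 0.45),
                   maf_range = c(0.3, 0.5), n_haplotypes_pool = 300,
                   error = error_config(uncertainty_level = 0,
                                        lowld_noise_sd = 1,
                                        lowld_r2_threshold = 0.3))
  sim <- simulate_paired_dataset(cfg)
  noised <- attr(sim$imputed, "noised")
  strong <- sim$truth$markers$rsid[sim$truth$block_id %in% c(1, 2)]
  weak <- sim$truth$markers$rsid[sim$truth$block_id %in% c(3, 4)]
  expect_length(intersect(noised, strong), 0)
  expect_setequal(noised, weak)
  # noised triplets still sum to one
  s <- sim$imputed$p_aa + sim$imputed$p_ab + sim$imputed$p_bb
  expect_true(all(abs(s - 1) < 1e-12))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- simulate_paired_dataset(small_cfg(seed = 33))
  b <- simulate_paired_dataset(small_cfg(seed = 33))
  c <- simulate_paired_dataset(small_cfg(seed = 34))
  expect_identical(a$truth$calls, b$truth$calls)
  expect_identical(a$imputed$p_ab, b$imputed$p_ab)
  expect_false(identical(a$truth$calls, c$truth$calls))
})

test_that("on-disk datasets round-trip and regenerate byte-identically", {
  cfg <- small_cfg(seed = 20)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out <- generate_paired_dataset(cfg, d1)
  expect_true(all(file.exists(unlist(out[names(out) != "data"]))))

  emp <- read_gen(out$empiric_gen)
  expect_equal(emp$markers$rsid, out$data$empiric$markers$rsid)
  expect_equal(emp$p_aa, out$data$empiric$p_aa,
               tolerance = 1e-4, ignore_attr = TRUE)
  ph <- read_sample(out$sample)
  expect_equal(sum(ph$status == 1), 120)

  man <- jsonlite::read_json(out$manifest)
  expect_equal(man$seed, 20)
  expect_equal(man$n_markers, 30)

  tr <- read.delim(out$truth)
  expect_equal(nrow(tr), 30)
  expect_true(all(c("block", "founder_maf", "flipped") %in% names(tr)))

  generate_paired_dataset(cfg, d2)
  for (f in c("empiric.gen", "imputed.gen", "cohort.sample", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("sim configurations round-trip through YAML", {
  cfg <- small_cfg(seed = 44,
                   causal = data.frame(block = 1, marker = 2, or = 1.4),
                   error = error_config(base_flip_prob = 0.05,
                                        differential = TRUE))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$causal$or, 1.4)
  expect_true(back$error$differential)
  expect_equal(back$error$base_flip_prob, 0.05)
  # the configuration hash agrees, so generation will too
  expect_identical(config_hash(back), config_hash(cfg))
})

test_that("invalid configurations are rejected up front", {
  expect_error(small_cfg(maf_range = c(0, 0.5)))
  expect_error(small_cfg(maf_range = c(0.05, 0.6)))
  expect_error(small_cfg(within_block_recomb = 0.7))
  expect_error(small_cfg(causal = data.frame(block = 99, marker = 1,
                                             or = 1.5)))
  expect_error(error_config(base_flip_prob = 1.5))
  expect_error(error_config(lowld_noise_sd = -1))
})
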