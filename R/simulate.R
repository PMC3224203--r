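# Synthetic paired empiric/imputed case-control GWAS generator.
#
# The generator emulates the statistical structure the audit assumes:
# LD-block haplotypes with tunable within-block r2, a case/control cohort
# drawn from a logistic disease model with GWA-scale per-allele odds
# ratios, and an imputed arm whose posterior triplets carry configurable
# error modes (posterior uncertainty, allele-label flips concentrated at
# MAF near 0.5, logit-scale noise in weak-LD blocks, optionally applied to
# controls only to induce false-positive associations).

#' Imputation-error configuration
#'
#' @param base_flip_prob Probability that a marker's imputed triplets have
#'   their allele labels swapped (pAA <-> pBB).
#' @param maf_flip_boost Additional flip probability for markers whose
#'   empiric MAF exceeds `maf_flip_threshold`, modeling major/minor allele
#'   ambiguity near MAF 0.5.
#' @param maf_flip_threshold Empiric-MAF threshold activating the boost.
#'   Default 0.45.
#' @param lowld_noise_sd Standard deviation of logit-scale Gaussian noise
#'   added to the posteriors of markers whose mean within-block r2 falls
#'   below `lowld_r2_threshold`. 0 disables.
#' @param lowld_r2_threshold Mean within-block r2 below which the low-LD
#'   noise applies. Default 0.2.
#' @param differential When `TRUE`, flips and noise are applied to control
#'   individuals only — the mechanism that turns label error into
#'   false-positive associations. Non-differential error mainly biases
#'   toward the null.
#' @param uncertainty_level Mixing weight toward the uninformative triplet
#'   (1/3, 1/3, 1/3). The default 0.075 yields a mean calling probability
#'   of about 0.95, the conventional post-imputation quality level.
#' @param flip_rsids Optional character vector of markers flipped
#'   deterministically (probability 1), for placing false positives at
#'   known locations.
#' @return An `error_config` list.
#' @export
error_config <- function(base_flip_prob = 0, maf_flip_boost = 0,
                         maf_flip_threshold = 0.45, lowld_noise_sd = 0,
                         lowld_r2_threshold = 0.2, differential = FALSE,
                         uncertainty_level = 0.075, flip_rsids = NULL) {
  probs <- c(base_flip_prob, maf_flip_boost, maf_flip_threshold,
             uncertainty_level)
  stopifnot(all(probs >= 0), all(probs <= 1), lowld_noise_sd >= 0,
            lowld_r2_threshold >= 0, lowld_r2_threshold <= 1,
            is.logical(differential))
  structure(list(base_flip_prob = base_flip_prob,
                 maf_flip_boost = maf_flip_boost,
                 maf_flip_threshold = maf_flip_threshold,
                 lowld_noise_sd = lowld_noise_sd,
                 lowld_r2_threshold = lowld_r2_threshold,
                 differential = differential,
                 uncertainty_level = uncertainty_level,
                 flip_rsids = flip_rsids),
            class = "error_config")
}

#' Simulation configuration
#'
#' Defaults emulate the cohort structure of a WTCCC-style case-control
#' scan: roughly 2 cases per 3 controls (2000 vs 3000), founder minor
#' allele frequencies uniform on (0.05, 0.5), and — when causal markers are
#' specified — per-allele odds ratios in the 1.2-1.6 range typical of
#' common-disease GWAS hits.
#'
#' @param n_blocks Number of LD blocks.
#' @param markers_per_block Markers per block.
#' @param n_haplotypes_pool Haplotype pool size. Default 200.
#' @param within_block_recomb Per-adjacent-marker recombination fraction in
#'   pool generation, in `[0, 0.5]`: 0 gives perfect within-block LD, 0.5
#'   free recombination (independent markers). A scalar or one value per
#'   block.
#' @param maf_range Lower/upper bound of the uniform founder MAF.
#' @param n_cases,n_controls Cohort sizes.
#' @param causal Optional `data.frame` with columns `block`, `marker`
#'   (1-based index within the block) and `or` (per-allele odds ratio of
#'   allele B).
#' @param error An [error_config()].
#' @param missing_rate Uniform missing-call rate in the empiric arm;
#'   missing calls are written as uninformative triplets. Default 0.
#' @param n_chrom Number of chromosomes the blocks are spread over
#'   (default `min(22, n_blocks)`).
#' @param seed Integer seed driving every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_blocks = 25, markers_per_block = 8,
                       n_haplotypes_pool = 200, within_block_recomb = 0.02,
                       maf_range = c(0.05, 0.5), n_cases = 2000,
                       n_controls = 3000, causal = NULL,
                       error = error_config(), missing_rate = 0,
                       n_chrom = NULL, seed = 1) {
  stopifnot(n_blocks >= 1, markers_per_block >= 1, n_haplotypes_pool >= 2,
            n_cases >= 1, n_controls >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            all(within_block_recomb >= 0), all(within_block_recomb <= 0.5),
            missing_rate >= 0, missing_rate < 1,
            inherits(error, "error_config"))
  if (!(length(within_block_recomb) %in% c(1L, n_blocks))) {
    stop("within_block_recomb must be a scalar or have one value per block")
  }
  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("block", "marker", "or") %in% names(causal)),
              all(causal$or > 0),
              all(causal$block >= 1), all(causal$block <= n_blocks),
              all(causal$marker >= 1),
              all(causal$marker <= markers_per_block))
  }
  if (is.null(n_chrom)) n_chrom <- min(22L, n_blocks)
  stopifnot(n_chrom >= 1, n_chrom <= 22)
  structure(list(
    n_blocks = n_blocks, markers_per_block = markers_per_block,
    n_haplotypes_pool = n_haplotypes_pool,
    within_block_recomb = within_block_recomb, maf_range = maf_range,
    n_cases = n_cases, n_controls = n_controls, causal = causal,
    error = error, missing_rate = missing_rate,
    n_chrom = as.integer(n_chrom), seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic sub-seed so each simulation stage has its own stream.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}

#' Simulate an LD-block haplotype pool
#'
#' Within a block, each haplotype is built left to right: the allele at a
#' marker is copied from the same haplotype's previous marker with
#' probability `1 - 2 r` (recombination-fraction semantics: r = 0 gives
#' perfect copying and pairwise r2 of 1 among markers with equal founder
#' frequencies; r = 0.5 gives free recombination and r2 of about 0) and is
#' otherwise drawn fresh from the marker's founder frequency. Blocks are
#' mutually independent and separated by at least 100 kb. Columns that come
#' out monomorphic are redrawn from their founder frequency (up to 10
#' tries).
#'
#' @param cfg A [sim_config()].
#' @return An object of class `haplotype_pool`: a list with `haplotypes`
#'   (binary matrix, haplotypes x markers), `markers`, `block_id`,
#'   `founder_maf` and `mean_block_r2` (per-marker mean r2 to the other
#'   markers of its block).
#' @export
simulate_haplotype_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 101))
  nb <- cfg$n_blocks; m <- cfg$markers_per_block
  pool <- cfg$n_haplotypes_pool
  recomb <- rep(cfg$within_block_recomb, length.out = nb)
  total <- nb * m

  haps <- matrix(0L, nrow = pool, ncol = total)
  founder <- numeric(total)
  block_id <- rep(seq_len(nb), each = m)
  for (b in seq_len(nb)) {
    cols <- which(block_id == b)
    f <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    founder[cols] <- f
    copy_prob <- max(0, 1 - 2 * recomb[b])
    hb <- matrix(0L, nrow = pool, ncol = m)
    hb[, 1] <- stats::rbinom(pool, 1, f[1])
    if (m > 1) {
      for (j in 2:m) {
        keep <- stats::runif(pool) < copy_prob
        fresh <- stats::rbinom(pool, 1, f[j])
        hb[, j] <- ifelse(keep, hb[, j - 1], fresh)
      }
    }
    haps[, cols] <- hb
  }
  # resample monomorphic columns (breaks their LD, keeps them usable)
  for (j in seq_len(total)) {
    tries <- 0
    while (length(unique(haps[, j])) == 1 && tries < 10) {
      haps[, j] <- stats::rbinom(pool, 1, founder[j])
      tries <- tries + 1
    }
    if (length(unique(haps[, j])) == 1) {
      stop("degenerate configuration: marker column ", j,
           " remained monomorphic after 10 resampling attempts")
    }
  }

  # marker map: blocks spread over n_chrom chromosomes, 4 kb within-block
  # spacing, 200 kb between blocks on the same chromosome
  chrom_of_block <- if (cfg$n_chrom == 1L) rep("1", nb) else {
    as.character(cut(seq_len(nb), breaks = cfg$n_chrom, labels = FALSE))
  }
  position <- integer(total)
  for (ch in unique(chrom_of_block)) {
    blocks_here <- which(chrom_of_block == ch)
    pos <- 1000000L
    for (b in blocks_here) {
      cols <- which(block_id == b)
      position[cols] <- pos + 4000L * (seq_along(cols) - 1L)
      pos <- pos + 4000L * length(cols) + 200000L
    }
  }
  alleles <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                    ncol = 2, byrow = TRUE)
  pick <- sample.int(4, total, replace = TRUE)
  markers <- marker_info(
    chrom = chrom_of_block[block_id],
    snp_id = sprintf("snp%06d", seq_len(total)),
    rsid = sprintf("rs%06d", seq_len(total)),
    position = position,
    allele_a = alleles[pick, 1], allele_b = alleles[pick, 2])

  mean_r2 <- mean_block_r2(haps, block_id)
  structure(list(haplotypes = haps, markers = markers, block_id = block_id,
                 founder_maf = founder, mean_block_r2 = mean_r2,
                 recomb = recomb),
            class = "haplotype_pool")
}

# Per-marker mean pairwise r2 to the other markers of its block, from the
# pool haplotypes; NA for single-marker blocks.
mean_block_r2 <- function(haps, block_id) {
  out <- rep(NA_real_, ncol(haps))
  for (b in unique(block_id)) {
    cols <- which(block_id == b)
    if (length(cols) < 2) next
    h <- haps[, cols, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(h)^2)
    diag(r2) <- NA
    out[cols] <- rowMeans(r2, na.rm = TRUE)
  }
  out
}

#' Simulate a case-control cohort from a haplotype pool
#'
#' Each individual is formed from two haplotypes drawn uniformly with
#' replacement; case/control status follows a logistic model whose
#' per-allele log odds come from `cfg$causal` and whose intercept is
#' calibrated to the target case fraction. The requested numbers of cases
#' and controls are reached by rejection sampling on status (batch draws,
#' capped at 50 batches).
#'
#' @param pool A [simulate_haplotype_pool()] result.
#' @param cfg The [sim_config()] used to build the pool.
#' @return A list with `truth` (class `true_genotypes`: `markers`, `calls`
#'   markers x individuals genotype codes 0/1/2 with NA for missing,
#'   `block_id`, `mean_block_r2`, `sample_ids`) and `pheno` (data.frame
#'   `id`, `status`).
#' @export
simulate_cohort <- function(pool, cfg) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 202))
  total <- ncol(pool$haplotypes)
  n_pool <- nrow(pool$haplotypes)
  target <- cfg$n_cases + cfg$n_controls
  prev <- cfg$n_cases / target

  causal_idx <- integer(0); beta <- numeric(0)
  if (!is.null(cfg$causal) && nrow(cfg$causal) > 0) {
    causal_idx <- (cfg$causal$block - 1L) * cfg$markers_per_block +
      cfg$causal$marker
    beta <- log(cfg$causal$or)
  }
  pool_freq <- colMeans(pool$haplotypes)
  intercept <- stats::qlogis(prev) -
    if (length(beta) > 0) sum(beta * 2 * pool_freq[causal_idx]) else 0

  calls_case <- NULL; calls_ctrl <- NULL
  got_case <- 0L; got_ctrl <- 0L
  batch <- max(200L, ceiling(1.5 * target))
  for (iter in seq_len(50)) {
    if (got_case >= cfg$n_cases && got_ctrl >= cfg$n_controls) break
    h1 <- sample.int(n_pool, batch, replace = TRUE)
    h2 <- sample.int(n_pool, batch, replace = TRUE)
    g <- pool$haplotypes[h1, , drop = FALSE] +
      pool$haplotypes[h2, , drop = FALSE]   # individuals x markers
    eta <- rep(intercept, batch)
    if (length(beta) > 0) {
      eta <- eta + g[, causal_idx, drop = FALSE] %*% beta
    }
    status <- stats::rbinom(batch, 1, stats::plogis(as.vector(eta)))
    need_case <- cfg$n_cases - got_case
    need_ctrl <- cfg$n_controls - got_ctrl
    take_case <- utils::head(which(status == 1), need_case)
    take_ctrl <- utils::head(which(status == 0), need_ctrl)
    if (length(take_case) > 0) {
      calls_case <- rbind(calls_case, g[take_case, , drop = FALSE])
      got_case <- got_case + length(take_case)
    }
    if (length(take_ctrl) > 0) {
      calls_ctrl <- rbind(calls_ctrl, g[take_ctrl, , drop = FALSE])
      got_ctrl <- got_ctrl + length(take_ctrl)
    }
  }
  if (got_case < cfg$n_cases || got_ctrl < cfg$n_controls) {
    stop("could not reach the requested cohort sizes within the ",
         "iteration cap; check the disease model")
  }
  calls <- t(rbind(calls_case, calls_ctrl))  # markers x individuals
  status <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  ids <- sprintf("ind%05d", seq_len(target))
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                   nrow = nrow(calls))
    calls[miss] <- NA_integer_
  }
  truth <- structure(list(markers = pool$markers, calls = calls,
                          block_id = pool$block_id,
                          mean_block_r2 = pool$mean_block_r2,
                          sample_ids = ids),
                     class = "true_genotypes")
  list(truth = truth, pheno = data.frame(id = ids, status = status,
                                         stringsAsFactors = FALSE))
}

# One-hot posterior triplets from genotype calls; missing calls become the
# uninformative triplet.
posterior_from_calls <- function(truth) {
  calls <- truth$calls
  na <- is.na(calls)
  p_aa <- (calls == 0) * 1; p_ab <- (calls == 1) * 1; p_bb <- (calls == 2) * 1
  p_aa[na] <- 1 / 3; p_ab[na] <- 1 / 3; p_bb[na] <- 1 / 3
  posterior_matrix(truth$markers, p_aa, p_ab, p_bb,
                   sample_ids = truth$sample_ids)
}

#' Emulate imputation output with configurable error modes
#'
#' Produces the imputed-arm posterior triplets from the true genotypes: the
#' one-hot triplet is mixed toward (1/3, 1/3, 1/3) by `uncertainty_level`;
#' allele-label flips (pAA <-> pBB) hit markers with probability
#' `base_flip_prob`, boosted above the MAF threshold, plus any markers in
#' `flip_rsids`; logit-scale Gaussian noise perturbs markers in weak-LD
#' blocks. With `differential = TRUE` flips and noise touch control
#' individuals only. Output triplets always sum to 1. Only the behavior of
#' an imputation algorithm's output is emulated, not its inference.
#'
#' @param truth A `true_genotypes` object from [simulate_cohort()].
#' @param pheno Phenotype `data.frame` aligned with the truth columns.
#' @param error An [error_config()].
#' @param seed Integer seed.
#' @return A [posterior_matrix()] with attributes `flipped` and `noised`
#'   (character vectors of affected rsids).
#' @export
emulate_imputation <- function(truth, pheno, error = error_config(),
                               seed = 1) {
  stopifnot(inherits(truth, "true_genotypes"),
            inherits(error, "error_config"))
  set.seed(derive_seed(seed, 303))
  m <- nrow(truth$calls); n <- ncol(truth$calls)
  u <- error$uncertainty_level
  na <- is.na(truth$calls)
  p_aa <- (truth$calls == 0) * (1 - u) + u / 3
  p_ab <- (truth$calls == 1) * (1 - u) + u / 3
  p_bb <- (truth$calls == 2) * (1 - u) + u / 3
  p_aa[na] <- 1 / 3; p_ab[na] <- 1 / 3; p_bb[na] <- 1 / 3

  f <- rowMeans(truth$calls, na.rm = TRUE) / 2
  emp_maf <- pmin(f, 1 - f)
  flip_prob <- error$base_flip_prob +
    error$maf_flip_boost * (emp_maf > error$maf_flip_threshold)
  flip <- stats::runif(m) < flip_prob
  if (!is.null(error$flip_rsids)) {
    flip <- flip | truth$markers$rsid %in% error$flip_rsids
  }
  target_cols <- if (error$differential) which(pheno$status == 0)
                 else seq_len(n)
  if (any(flip)) {
    tmp <- p_aa[flip, target_cols, drop = FALSE]
    p_aa[flip, target_cols] <- p_bb[flip, target_cols, drop = FALSE]
    p_bb[flip, target_cols] <- tmp
  }

  noised <- rep(FALSE, m)
  if (error$lowld_noise_sd > 0) {
    noised <- !is.na(truth$mean_block_r2) &
      truth$mean_block_r2 < error$lowld_r2_threshold
    if (any(noised)) {
      idx <- which(noised)
      nr <- length(idx); nc <- length(target_cols)
      jitter <- function(p) {
        exp(log(pmax(p[idx, target_cols, drop = FALSE], 1e-8)) +
              matrix(stats::rnorm(nr * nc, sd = error$lowld_noise_sd),
                     nr, nc))
      }
      a <- jitter(p_aa); b <- jitter(p_ab); c <- jitter(p_bb)
      s <- a + b + c
      p_aa[idx, target_cols] <- a / s
      p_ab[idx, target_cols] <- b / s
      p_bb[idx, target_cols] <- c / s
    }
  }
  out <- posterior_matrix(truth$markers, p_aa, p_ab, p_bb,
                          sample_ids = truth$sample_ids)
  attr(out, "flipped") <- truth$markers$rsid[flip]
  attr(out, "noised") <- truth$markers$rsid[noised]
  out
}

#' Simulate a complete paired dataset in memory
#'
#' Runs pool, cohort and imputation emulation and returns every object the
#' downstream pipeline needs.
#'
#' @param cfg A [sim_config()].
#' @return A list with `empiric` and `imputed` (posterior matrices),
#'   `pheno`, `truth`, `pool` and `config`.
#' @export
simulate_paired_dataset <- function(cfg) {
  pool <- simulate_haplotype_pool(cfg)
  cohort <- simulate_cohort(pool, cfg)
  empiric <- posterior_from_calls(cohort$truth)
  imputed <- emulate_imputation(cohort$truth, cohort$pheno, cfg$error,
                                seed = cfg$seed)
  list(empiric = empiric, imputed = imputed, pheno = cohort$pheno,
       truth = cohort$truth, pool = pool, config = cfg)
}

# Tiny FNV-1a hash of a string; used only to fingerprint configurations in
# run manifests.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keeps h in double range
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in two 16-bit halves (stays within double
    # precision, unlike a direct 2^32-range product)
    h_lo <- h %% 65536
    h_hi <- h %/% 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(cfg) {
  plain <- unclass(cfg)
  plain$error <- unclass(plain$error)
  fnv1a(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA))
}

#' Generate a paired dataset on disk
#'
#' Writes the empiric arm as hard-call (one-hot) GEN triplets, the imputed
#' arm as soft GEN triplets, the cohort SAMPLE file, a marker-level truth
#' sidecar TSV (block, founder MAF, causal effect, applied error modes) and
#' a JSON manifest recording the seed and a configuration hash.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the file paths plus the in-memory
#'   dataset under `$data`.
#' @export
generate_paired_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_paired_dataset(cfg)
  paths <- list(
    empiric_gen = file.path(dir, "empiric.gen"),
    imputed_gen = file.path(dir, "imputed.gen"),
    sample = file.path(dir, "cohort.sample"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_gen(sim$empiric, paths$empiric_gen)
  write_gen(sim$imputed, paths$imputed_gen)
  write_sample(sim$pheno, paths$sample)

  causal_or <- rep(NA_real_, n_markers(sim$empiric))
  if (!is.null(cfg$causal) && nrow(cfg$causal) > 0) {
    idx <- (cfg$causal$block - 1L) * cfg$markers_per_block + cfg$causal$marker
    causal_or[idx] <- cfg$causal$or
  }
  truth_tab <- cbind(sim$truth$markers, data.frame(
    block = sim$truth$block_id,
    founder_maf = sim$pool$founder_maf,
    mean_block_r2 = sim$truth$mean_block_r2,
    causal_or = causal_or,
    flipped = sim$truth$markers$rsid %in% attr(sim$imputed, "flipped"),
    noised = sim$truth$markers$rsid %in% attr(sim$imputed, "noised")))
  data.table::fwrite(truth_tab, paths$truth, sep = "\t", quote = FALSE,
                     na = "NA")
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   n_markers = n_markers(sim$empiric),
                   n_individuals = n_individuals(sim$empiric),
                   n_cases = cfg$n_cases, n_controls = cfg$n_controls,
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, list(data = sim)))
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  err <- do.call(error_config, as.list(y$error %||% list()))
  y$error <- err
  if (!is.null(y$causal)) y$causal <- as.data.frame(y$causal)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$error <- unclass(plain$error)
  if (!is.null(plain$causal)) plain$causal <- as.list(plain$causal)
  yaml::write_yaml(plain, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
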