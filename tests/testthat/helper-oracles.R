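# Independent brute-force oracles used to cross-check the package's own
# statistics. These deliberately use different code paths (base R tests,
# rank formulas, exhaustive enumeration) than the implementation.

# Cochran-Armitage trend chi-square via stats::prop.trend.test.
oracle_trend <- function(case, control) {
  unname(stats::prop.trend.test(case, case + control,
                                score = c(0, 1, 2))$statistic)
}

# Pearson chi-square without continuity correction.
oracle_chisq <- function(tab) {
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

# Allelic odds ratio by direct cross-product on allele counts, minor
# allele as exposure.
oracle_allelic_or <- function(case, control) {
  cb <- case[2] + 2 * case[3]; ca <- 2 * case[1] + case[2]
  kb <- control[2] + 2 * control[3]; ka <- 2 * control[1] + control[2]
  if ((cb + kb) / (ca + cb + ka + kb) <= 0.5) {
    (cb * ka) / (ca * kb)
  } else {
    (ca * kb) / (cb * ka)
  }
}

# Spearman through the definition: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# r2 as the squared Pearson correlation of the binary haplotype vectors.
oracle_r2 <- function(a, b) stats::cor(a, b)^2

# Exact one-sided Mann-Whitney p-value (group x larger) by enumerating
# every assignment of the pooled values to the two groups.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  obs <- sum(r[seq_len(m)])
  sums <- utils::combn(length(pooled), m,
                       FUN = function(idx) sum(r[idx]))
  mean(sums >= obs)
}

# A random fractional-free genotype count table with strictly positive
# cells (so no continuity corrections are triggered).
random_counts <- function() {
  list(case = stats::rpois(3, 25) + 1, control = stats::rpois(3, 25) + 1)
}
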