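---
title: "Methods: auditing imputed association statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing imputed association statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genotype imputation fills in untyped SNPs from typed flanking markers and a
reference haplotype panel, returning per-genotype posterior probabilities
rather than hard calls. Association scans routinely test these imputed
markers as if they had been genotyped. `imputeaudit` quantifies what that
substitution does to case-control association statistics: for every marker
available in both forms, it computes the association test twice — once from
the directly genotyped ("empiric") calls and once from the imputed
posteriors — and measures the disagreement.

The central quantity is the **bias**

$$\mathrm{bias} = (-\log_{10} p_{\mathrm{emp}}) - (-\log_{10} p_{\mathrm{imp}}),$$

negative when the imputed statistic overstates significance. At a fixed
threshold $\alpha$ each marker is classified by which arm(s) call it
significant (strict inequality $p < \alpha$): `concordant_sig`,
`concordant_null`, `discordant_imp_only`, `discordant_emp_only`. The
`discordant_imp_only` class is the dangerous one — apparent discoveries
unsupported by direct genotyping.

## Association statistics from posterior-expected counts

Imputed genotypes are probability triplets $(p_{AA}, p_{AB}, p_{BB})$.
Rather than thresholding them into hard calls, every test statistic is
computed from the **posterior-expected genotype count table**: the case row
is $\sum_{i \in \mathrm{cases}} (p_{AA,i}, p_{AB,i}, p_{BB,i})$ and likewise
for controls. For one-hot triplets this reduces exactly to ordinary counts,
so the empiric and imputed arms share a single code path
(`expected_counts()`, `run_association()`).

Four inheritance models are available (`model_test()`):

* **codominant** — Pearson chi-square on the full 2×3 table (2 df);
* **dominant** — 2×2 collapse {AA} vs {AB, BB} with respect to allele B;
* **recessive** — 2×2 collapse {AA, AB} vs {BB};
* **log-additive** — Cochran–Armitage trend test with scores (0, 1, 2),
  the headline model throughout.

Supporting per-marker quantities: pooled minor allele frequency (capped at
0.5), mean-maximum-posterior calling quality, a 1-df Hardy–Weinberg test on
integer-rounded pooled counts, and the allelic odds ratio with the minor
allele as exposure. Odds ratios are also reported **coined** —
$\max(\mathrm{OR}, 1/\mathrm{OR})$ — with the direction (protective vs
susceptibility) kept separately, so magnitudes are comparable across
markers. Collapsed 2×2 tables with a zero margin receive the
Haldane–Anscombe 0.5 correction and carry a flag.

## Downstream diagnostics

* **Concordance accounting** (`concordance_table()`, `threshold_sweep()`,
  `rank_correlation()`): the 2×2 significance cross-classification, per-arm
  significant totals across thresholds, and the Spearman correlation of the
  paired $-\log_{10} p$ values.
* **Predictor scans** (`predictor_scan()`, `extreme_maf_subset()`): which
  marker-level quality metrics anticipate large $|\mathrm{bias}|$. Allele
  ambiguity makes MAF near 0.5 a particular risk: an A/B label swap at
  MAF exactly 0.5 is undetectable from frequencies alone.
* **Haplotypic blocks** (`build_blocks()`, `block_summary()`,
  `summary_vs_bias()`): here a marker's "block" is the complete multiset of
  pairwise $r^2$ values involving it (both endpoints of every LD record
  collect the value), summarized by mean, median, max and *population*
  variance ($\div n$, a descriptive summary of a complete multiset, not an
  estimate from a sample). Weak local LD starves imputation of information,
  so low block summaries should predict disagreement.
* **Sliding windows** (`build_windows()`, `compare_window_groups()`): a
  truly associated marker sits among associated neighbours; an isolated
  significant imputed marker is suspect. For each imputed-significant
  center, the window collects the $-\log_{10}$ imputed p-values of the $k$
  nearest same-chromosome markers per side (at most $2k$ flanks, fewer at
  edges) and summarizes them by sum, mean and *sample* variance ($n-1$;
  set to 0 with a `low_flank` flag below 2 flanks, where dispersion is
  meaningless). Concordant vs discordant centers are compared with a
  one-sided Wilcoxon–Mann–Whitney test (exact for combined $n \le 20$
  without ties). The flank **sum** is the most robust discriminator, since
  it rewards both the magnitude and the number of supporting neighbours.

## The synthetic generator

Auditing real discovery scans requires restricted cohort data, so the
package ships a generator (`sim_config()`, `simulate_paired_dataset()`)
that reproduces the *statistical structure* the audit depends on. It
emulates the output of an imputation algorithm, never its inference.

**Haplotype pool.** Markers live in LD blocks. Within a block, each pool
haplotype is built left to right: the allele at a marker copies the
previous marker's allele with probability $c = \max(0, 1 - 2r)$ and is
otherwise drawn fresh from the marker's founder frequency.
`within_block_recomb` $r$ uses recombination-fraction semantics: $r = 0$
gives perfect copying (pairwise $r^2 = 1$), $r = 0.5$ free recombination
(independent markers, $r^2 \approx 0$); the linear map $1 - 2r$ is the
simplest interpolation with those endpoints. Blocks are independent,
spread over up to 22 chromosomes, 4 kb between markers and 200 kb between
blocks.

**Cohort.** Individuals are two pool haplotypes drawn with replacement;
status follows a logistic model with per-allele log odds from the `causal`
table and an intercept calibrated to the case fraction; exact case/control
counts come from batched rejection sampling. Note one consequence of the
finite pool: cohort genotypes at different markers are coupled through
shared pool rows, so scenarios that need effectively independent markers
(e.g. calibration checks against binomial bands) must make the pool large
relative to the number of haplotype draws.

**Imputed arm error modes** (`error_config()`), composable and
individually switchable:

* `uncertainty_level` mixes each one-hot triplet toward (1/3, 1/3, 1/3).
  The default 0.075 yields a mean calling probability of 0.95, the
  conventional post-imputation quality level — chosen so that, by default,
  the imputed arm is realistic rather than error-free.
* Allele-label flips (`base_flip_prob`, plus `maf_flip_boost` above
  `maf_flip_threshold` = 0.45, plus deterministic `flip_rsids`) swap
  $p_{AA} \leftrightarrow p_{BB}$, modeling strand/label ambiguity that
  concentrates near MAF 0.5.
* Logit-scale Gaussian noise (`lowld_noise_sd`) perturbs markers whose
  mean within-block $r^2$ falls below `lowld_r2_threshold` = 0.2.
* `differential = TRUE` applies flips and noise to controls only. This is
  the mechanism that converts label error into *false-positive*
  associations; non-differential error mainly attenuates toward the null.

Every stage derives its own seed deterministically from the master seed,
so whole datasets regenerate byte-identically.

## Numerical and format conventions

* Oxford GEN files: both the 5-column and 6-column dialects are
  auto-detected; probability triplets are renormalized silently when their
  sum is within $10^{-4}$ of 1, with a warning up to $10^{-2}$, and
  rejected beyond that. Markers are sorted by (chromosome, position) on
  load. Written GEN files use the 6-column dialect with 4 decimals.
* Results TSVs print p-values with `%.16e` and other doubles with `%.17g`,
  so `write_results()` / `read_results()` round-trip losslessly — byte
  identity of results files is the package's determinism check.
* $-\log_{10}$ of an exactly-zero p-value (numeric underflow of extreme
  imputed statistics) is clipped at $10^{-300}$ with a warning.
* Significance is always the strict inequality $p < \alpha$.

## Problem sizes

The defaults target desk scale: simulated scans of roughly 200–5,000
markers and 300–5,000 individuals run in seconds to a few minutes on one
CPU, with the association kernels vectorized across markers. These sizes
are the package's own choices for tractable, reproducible analysis; the
statistics themselves do not depend on them.

## Limitations

* The generator does not model reference-panel mismatch, imputation-window
  effects, genotyping batch effects or population stratification; its
  error modes are stylized levers, not a forward model of any particular
  imputation algorithm.
* The HWE test uses the 1-df chi-square approximation on rounded counts,
  not an exact test; it is a filter ingredient, not an inference target.
* Posterior-expected count tables treat fractional counts as if they were
  observed; no information-measure correction for imputation uncertainty
  is applied — that uncorrected behavior is precisely the practice the
  audit measures.
* The sliding-window diagnostic presumes dense marker coverage around
  centers; isolated markers at chromosome edges yield few flanks and are
  flagged rather than adjudicated.
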