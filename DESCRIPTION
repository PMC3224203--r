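Package: imputeaudit
Title: Auditing Genotype Imputation Accuracy for GWAS Association Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Paired empiric-versus-imputed association testing for
    case-control genome-wide association studies. Reads Oxford GEN/SAMPLE
    genotype-probability files, computes per-SNP association statistics
    under codominant, dominant, recessive and log-additive inheritance
    models from posterior-expected genotype counts, classifies markers as
    concordant or discordant between the directly genotyped and the
    imputed arm, and provides marker-level quality filters, predictor
    scans, linkage-disequilibrium block summaries and a sliding-window
    procedure that flags false-positive imputed associations from the
    association statistics of flanking markers. A synthetic case-control
    GWAS generator with controllable imputation-error modes (allele-label
    flips, posterior uncertainty, low-LD noise, differential error) makes
    every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
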