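Package: transloci
Title: Cross-Population Generalizability of Known GWAS Risk Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether established GWAS susceptibility loci
    generalize across ancestrally diverse case-control populations.
    Implements per-variant log-additive logistic association within
    case-control strata with minor-allele-frequency and imputation-quality
    filters, fixed-effects inverse-variance meta-analysis within and across
    populations, exact binomial tests of directional consistency against
    reported risk alleles, LD-proxy regional replication with greedy
    pairwise tag-SNP binning and tag-count-derived significance thresholds,
    unweighted allele-count genetic risk scores (including variants that
    substitute regionally significant lead SNPs), and analytic power for the
    per-allele case-control test. A multi-population synthetic cohort
    generator (Balding-Nichols allele-frequency divergence, latent-Gaussian
    block LD, a logistic disease model, chip-specific missingness and
    imputation INFO scores) makes the whole pipeline testable end to end
    without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
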