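Package: gfrloci
Title: Single-Cohort Characterization of Kidney-Function GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Follow-up analysis of known kidney-function loci in a single
    population cohort. Builds analysis-ready phenotypes (instrument- and
    period-normalized serum creatinine, eGFR from the 2009 CKD-EPI equation
    winsorized at 15 and 200 ml/min/1.73m2 and log-transformed, rank-based
    inverse-normal trait scores), re-tests meta-analysis loci with one-sided
    covariate-adjusted regressions and linkage-disequilibrium proxy
    selection, compares cohort against meta-analysis effects via
    inverse-variance leave-cohort-out subtraction and explained-variance
    ratios, screens quantitative traits as candidate mediators with the
    four-step regression framework and a stringent Tukey outlier rule on
    adjusted effects, and tests SNP-by-thyroid-function interactions.
    Includes a synthetic-cohort generator with known ground truth so every
    stage is testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ggplot2,
    yaml,
    jsonlite
Config/testthat/edition: 3
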