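Package: mrsummary
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-sample (separate-sample)
    Mendelian randomization from GWAS summary statistics: reading and
    harmonizing per-variant association tables, instrument selection
    (genome-wide significance, LD pruning, pleiotropy exclusion lists,
    proxy substitution), per-variant F statistics, causal-effect
    estimation by Wald ratio, fixed-effect inverse-variance weighting,
    generalized weighted regression for correlated variants, weighted
    median and MR-Egger regression, Fieller confidence sets, Cochran's Q
    heterogeneity and Egger-intercept pleiotropy diagnostics, power and
    minimal detectable odds-ratio calculations for binary outcomes, and
    Bonferroni correction. Includes a summary-statistics simulator with
    configurable causal effect, pleiotropy regimes and LD structure so
    every stage is testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
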