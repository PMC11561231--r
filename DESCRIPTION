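Package: cismr
Title: Cis-Mendelian Randomisation of Protein Drug Targets from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for drug-target cis-Mendelian randomisation from
    GWAS summary statistics, built around the sclerostin (SOST) worked
    example. Provides summary-statistics input, quality control and allele
    harmonisation; fixed- and random-effects inverse-variance-weighted
    meta-analysis with Cochran's Q, I-squared and genomic-inflation
    diagnostics; cis-instrument selection by greedy LD clumping with
    F-statistics; causal-effect estimation via the Wald ratio, generalised
    IVW honouring instrument correlation, and principal-component MR;
    approximate-Bayes-factor colocalization over a cis-region; per-variant
    linear, logistic and Cox association models for individual-level
    cohorts; and a synthetic-data generator producing LD-structured
    regional summary statistics and biobank-like cohorts with known causal
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
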