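Package: chemomr
Title: Two-Sample Mendelian Randomization of Plasma Chemokines on Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested two-sample Mendelian randomization workflow for panels of
    circulating protein exposures (plasma chemokines) against disease risk and
    survival outcomes supplied as GWAS summary statistics. Provides instrument
    selection at genome-wide significance with greedy LD pruning and
    instrument-strength statistics (per-SNP R2 and the F statistic), allele
    harmonization with palindromic-SNP handling, the estimator suite (Wald
    ratio with delta-method SE, fixed-effect inverse-variance weighting,
    MR-Egger regression, weighted median with parametric-bootstrap SE),
    Cochran's Q / I2 heterogeneity, Bonferroni correction across an exposure
    panel, and weighted polygenic-risk-score construction with tertile
    categorization. A synthetic summary-statistics and cohort generator with
    known causal effects gives the whole pipeline a download-free test
    surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
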