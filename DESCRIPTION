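Package: mrpath
Title: Two-Sample Mendelian Randomization with Sensitivity Diagnostics and
    Two-Step Mediation from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection with LD clumping and proxy substitution,
    allele harmonization with palindromic-variant handling, Steiger
    directionality filtering and radial outlier removal, five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode, robust adjusted profile score), heterogeneity and
    pleiotropy diagnostics (Cochran's and Ruecker's Q, Egger intercept,
    MR-PRESSO, leave-one-out, confounder-associated instrument exclusion),
    and two-step mediation with product-of-coefficients indirect effects and
    delta-method standard errors. Includes a synthetic two-sample GWAS
    summary-statistics generator with known ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
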