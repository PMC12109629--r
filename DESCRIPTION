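Package: mrmediation
Title: Two-Sample Two-Step Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    MR mediation analysis from GWAS summary statistics. Implements reading
    and harmonization of summary statistics, instrument selection
    (genome-wide significance, LD clumping, F-statistic filtering), five MR
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode), sensitivity diagnostics (Cochran Q, Egger
    intercept, leave-one-out, MR-PRESSO outlier detection), a screening
    cascade over many exposure-outcome pairs, and product-of-coefficients
    mediation with delta-method confidence intervals. A synthetic
    summary-statistic generator with known causal truth supports end-to-end
    validation without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
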