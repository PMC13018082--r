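Package: coseglr
Title: Co-Segregation Likelihood Ratios for Variant Classification in
    Cancer Predisposition Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Survival-based full-pedigree co-segregation analysis for
    classifying variants of uncertain significance in BRCA1, BRCA2 and
    PALB2. Reads pedigrees in CanRisk tabular format, models age-specific
    cancer penetrance with scaled truncated-normal curves fitted to
    incidence-rate tables, handles multiple cancers per individual
    (including a conditional constant-hazard model for contralateral
    breast cancer), enumerates Mendelian genotype configurations of a
    rare dominant variant, and reports the likelihood ratio of the
    observed genotypes under the pathogenic versus benign hypothesis,
    with conversion to ACMG/AMP co-segregation evidence strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
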