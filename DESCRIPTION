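Package: reprometa
Title: Reproduction and Agreement Analysis of Meta-Analytic Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reproducing published meta-analyses from study-level
    data and auditing how closely the reproduced results match the originally
    reported ones. Computes per-study effect estimates (mean differences,
    standardised mean differences, log odds/risk ratios) from arm-level
    summary statistics or from reported estimates with confidence intervals;
    pools them under fixed- or random-effects models (inverse-variance or
    Mantel-Haenszel, with DerSimonian-Laird, REML, or Paule-Mandel
    heterogeneity estimators and Wald or Hartung-Knapp intervals); resolves
    incompletely reported method details through an auditable, ordered rule
    table; classifies each reproduction attempt against the original report
    using relative-difference thresholds and meaningful-difference rules;
    and summarises agreement across a corpus with Bland-Altman limits of
    agreement, Banksia scaling, P-value significance-band concordance, and
    Clopper-Pearson exact binomial confidence intervals. A synthetic-review
    generator with configurable reporting information loss supports
    end-to-end evaluation of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
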