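Package: semscan
Title: Stochastic Epigenetic Mutation Analysis for Twin Methylation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects stochastic epigenetic mutations (SEMs) in DNA methylation
    beta-value matrices using per-probe interquartile-range outlier thresholds,
    summarises per-subject hypo- and hyper-methylation burdens, compares
    burdens between groups with family-level mixed-effects models, scans for
    genomic regions enriched in same-direction epimutations, performs
    three-population gene-set comparisons and candidate-gene screens, and runs
    a simplified paired differential-methylation analysis. Includes a
    twin-structured synthetic-data generator with known spiked epimutations
    and a packaged congenital-hypothyroidism twin cohort table for worked
    examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    sandwich,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
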