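Package: flyspan
Title: Lifespan, Stress-Resistance and Circadian Activity Analysis for
    Drosophila Longevity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for Drosophila melanogaster longevity
    studies of the Gclc (glutamate-cysteine ligase) neuronal-overexpression
    design. Summarizes survival cohorts recorded on a census grid (mean,
    SEM, median, time of 90% mortality), compares median and maximum
    lifespan between genotypes (weighted log-rank and the Wang-Allison
    Fisher-exact quantile test), quantifies the age-dependent decline of
    stress resistance through Pearson age-survival correlations and
    Fisher-z comparison of correlation coefficients, aggregates gene-level
    log fold-changes onto multi-gene KEGG pathway nodes by
    expression-weighted averaging, and summarizes Drosophila Activity
    Monitor (DAM) recordings into binned series, zeitgeber-aligned daily
    profiles and actogram matrices. A synthetic-data module generates
    every input the pipeline consumes, so all stages run reproducibly
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
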