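Package: vteprs
Title: Case-Control SNP-Panel Association and Polygenic Risk Scoring for
    Venous Thromboembolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for a curated-panel case-control study of
    venous thromboembolism (VTE): per-variant genotyping quality control
    (call rate, Hardy-Weinberg exact test in controls), allelic and
    genotype-model association statistics (odds ratios with Woolf or exact
    conditional confidence intervals, chi-square/Fisher test selection,
    covariate-adjusted logistic estimates), retrospective power calculation
    for the allelic test, a log-odds-weighted polygenic risk score with
    control-referenced standardization, and PRS-stratified two-year
    recurrence survival analysis (Kaplan-Meier, log-rank, Cox). A synthetic
    cohort generator emulating the study's statistical structure makes every
    stage testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
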