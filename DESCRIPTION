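Package: pvsignal
Title: Disproportionality Screening and Time-to-Onset Modelling for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal screening in spontaneous
    reporting system (SRS) databases distributed as JADER-style relational
    tables (DEMO, DRUG, REAC, HIST). Loads, validates and deduplicates
    reports, restricts to suspected-drug exposures with configurable route
    eligibility, aggregates MedDRA preferred terms into Standardized MedDRA
    Query (SMQ) groups with once-per-report counting, and screens drug-event
    pairs by proportional reporting ratio (PRR), Yates-corrected chi-squared,
    reporting odds ratio (ROR) with Woolf confidence intervals, and the
    Bayesian information component (IC) with its lower credibility bound
    (IC025). P-values are handled entirely on the log scale, including a
    log-space Benjamini-Hochberg false discovery rate adjustment, and a
    four-condition decision rule flags signals. Time-to-onset distributions
    are modelled with two-parameter Weibull fits, Wald confidence intervals,
    hazard-shape (failure type) classification and an Anderson-Darling
    goodness-of-fit test. A synthetic SRS generator with planted
    reporting-rate multipliers and onset distributions provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    yaml,
    jsonlite,
    fitdistrplus,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
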