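Package: injurychain
Title: First-Order Markov Analysis of Subsequent Injury Risk from
    Time-Loss Injury Surveillance Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing subsequent-injury (including re-injury)
    patterns in time-loss injury surveillance data coded in the
    consensus-statement style used in professional football. Reads and
    validates per-injury records, applies standard cleaning and exclusion
    rules (label normalisation, contact-injury exclusion, side-qualified
    body parts, removal of single-injury player-seasons), builds
    date-ordered per-player per-season injury sequences, estimates
    first-order Markov transition probabilities between injury states
    under explicit denominator conventions with binomial proportion
    confidence intervals, classifies transitions into the three standard
    subsequent-injury scenarios, and renders transition-matrix and
    confidence-interval reports. A synthetic cohort generator with a
    known transition kernel makes the whole pipeline testable without
    access to any private surveillance dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
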