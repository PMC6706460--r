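Package: ntgs
Title: Genome-Sequencing Variant Analysis for Prenatal Diagnosis of Fetuses
    with Increased Nuchal Translucency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-backed implementation of a
    genome-sequencing (~30-fold) prenatal-diagnosis analysis for fetuses
    with increased nuchal translucency. Provides read-depth copy-number
    variant detection on 5-kb windows with sliding-window candidate scans,
    breakpoint refinement by coverage-step maximization, rank-sum rarity
    testing against a reference panel, and mosaic-fraction quantification
    from copy ratios; chimeric read-pair structural-variant detection with
    clustering and a systematic/random/orientation filter cascade;
    rule-based small-variant prioritization, trio inheritance and
    compound-heterozygote phasing, and five-tier classification; and
    cohort diagnostic-yield statistics with exact binomial confidence
    intervals, ISCN-style nomenclature emission, and delta-delta-Ct qPCR
    copy-ratio validation. A synthetic-data module generates every input
    with known truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
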