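Package: vioscales
Title: Violence-Situation Typology and Reproducibility of
    Functional-Impairment Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how consistently 7-level Likert scales of
    functional impairment are rated in forensic consultations of individuals
    exposed to violence.  The package builds a typology of violence
    situations from mixed consultation features (Gower dissimilarity,
    partitioning around medoids, consensus resampling with a multimetric
    choice of the number of profiles), measures profile-matched inter- and
    intra-rater concordance with the tie-corrected Kendall coefficient of
    concordance, and characterises the scales (medians and IQR,
    Kruskal-Wallis with Conover-Iman post hoc tests, univariate regressions
    on days of total incapacity to work).  Because consultation records of
    this kind are private, a synthetic-cohort generator reproduces the
    latent-profile, rater-effect and outcome structure the analysis assumes,
    including lexicon-minable certificate free text, so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
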