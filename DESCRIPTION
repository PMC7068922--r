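Package: spiderplan
Title: Radiotherapy Plan Quality Scoring, Radar Comparison and Preference-Based Weight Elicitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores radiotherapy treatment plans against protocol dose-tolerance
    criteria, aggregates structure scores into weighted group and global plan
    scores, and compares competing plans with an equivalence threshold on the
    global-score difference. Group importance weights can be elicited
    automatically from clinician pairwise plan preferences through an exact
    ideal-point mixed-integer program, and rater consistency is quantified with
    Brennan-Prediger agreement coefficients (nominal and weighted ordinal) on
    the Landis-Koch scale. Radar diagrams display structure- and group-level
    scores for one or more plans against the unit reference contour. Includes a
    synthetic-data generator for plans, preferences and rating tables with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
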