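Package: gradespread
Title: Social Contagion of Academic Achievement in Friendship Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a student's social environment relates to
    their academic progress. Reads tiered sociometric survey data (best
    friend / friend / acquaintance ratings) and two-timepoint GPA records,
    transforms GPAs into class rankings, computes per-student neighbourhood
    rank-environment statistics, fits a four-predictor progress regression
    with a sequential (Type I) ANOVA decomposition, and tests the
    friend-environment/progress correlation against an out-degree-preserving
    network-randomization null model with an empirical permutation p-value.
    Includes a synthetic cohort generator with an optional planted contagion
    effect so the full pipeline runs without access to restricted student
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
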