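Package: starmaze
Title: Star-Maze Virtual-Reality Navigation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immersive virtual-reality star-maze
    navigation experiments in children, including clinical cohorts with
    cerebral palsy. Scores per-trial 2-D trajectories (success, visited
    alleys, total path length, distance error, rotation angle), classifies
    spontaneous navigation strategy (allocentric, egocentric, shifter,
    no-strategy) from interposed testing trials, scores compelled-strategy
    trials, detects the learning-curve stabilization trial with Friedman
    testing, and runs the nonparametric group-comparison battery
    (chi-square, Kruskal-Wallis with Bonferroni-corrected Mann-Whitney post
    hocs, paired Wilcoxon, delta scores). A goal-directed agent simulator
    generates synthetic cohorts with ground-truth strategy and learning
    labels so the full pipeline is testable without access to recorded
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
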