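Package: povdyn
Title: Household Poverty Dynamics from Two-Round Smallholder Farm Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing poverty dynamics in two-round panel surveys of
    smallholder farm households. Computes household food-availability and
    total-value-of-activities indicators from crop, livestock and off-farm
    records (with male-adult-equivalent and tropical-livestock-unit
    normalisation), classifies households into three poverty strata using a
    calorie line and the international poverty line, assigns nine-group panel
    trajectories, scores standard welfare instruments (HFIAS, HDDS, PPI
    scorecards, hungry months) for stratum validation, and provides the paired
    and group-comparison statistics used for panel analysis (McNemar,
    Wilcoxon signed rank, one-way ANOVA with Tukey HSD or Fisher LSD post-hoc
    letters, asset-income regressions). A synthetic panel generator with
    designed strata proportions and transition structure makes the whole
    pipeline testable without access to archived survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
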