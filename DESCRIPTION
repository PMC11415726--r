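Package: habitvr
Title: Headless Simulation and Movement Analytics for Home-Based Bimanual
    Virtual Reality Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seedable, headless re-implementation of a home-based bimanual
    upper-extremity rehabilitation game of the HABIT-VR family (rocket
    shooting with adaptive difficulty, target-score motivation, power-ups and
    a chained boss battle), together with the full measurement chain used to
    evaluate such interventions: a parametric virtual player with two-stage
    motor learning that generates per-attempt event logs and per-hand 3-axis
    controller accelerometry, adherence and dose accounting over a study
    calendar, an open activity-counts pipeline with youth intensity cutoffs
    (light vs moderate-to-vigorous physical activity), and single-case
    three-phase statistics (phase summaries, percent change, Cohen's d with
    interpretation bands, per-phase trends, and COPM goal-table analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
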