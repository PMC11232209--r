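Package: rehabpose
Title: Pose-Landmark Movement Assessment and Trial Statistics for
    Tele-Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for AI-assisted tele-rehabilitation of older adults
    with sarcopenia. Reads and validates 33-landmark 3D pose streams,
    smooths trajectories, reduces them to a 17-keypoint skeleton with a
    hip-midpoint centre of gravity, extracts cosine-rule joint angles,
    builds instructor movement templates on a normalized-time grid, and
    detects and verbalizes directional joint-angle deviations in learner
    sessions. Also implements the supporting clinical trial machinery:
    AWGS 2019 sarcopenia screening, outcome-battery scoring, stratified
    randomization, session scheduling, mixed repeated-measures ANOVA with
    Mauchly's sphericity test and a Pillai's-trace fallback, partial
    eta-squared effect sizes, pairwise mean differences, and
    noncentral-F power analysis with a sample-size solver. A synthetic
    motion and cohort generator provides fully scripted test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
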