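Package: growthtraj
Title: Longitudinal Growth Trajectories Under ADHD Pharmacotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying age- and sex-standardized weight and height
    trajectories in children and adolescents with ADHD treated with
    guanfacine, stimulants, or no pharmacotherapy, using EMR-style extracts.
    Implements new-user cohort derivation with washout and censoring rules,
    drug-exposure episode construction with seasonal gap allowances,
    prescribed-amount and medication possession ratio computation with an
    overlap cap, LMS (Box-Cox) growth-chart standardization against CDC-style
    reference tables, random-coefficients mixed models of z-score
    trajectories, pre/post treatment-initiation models, and classification of
    individual percentile-line shifts. A seeded synthetic-EMR generator
    emulates the extract structure so the whole pipeline is testable without
    access to protected records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
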