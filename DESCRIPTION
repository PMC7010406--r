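Package: seqreach
Title: Simulation and Analysis of Sequential Reaching Task Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying memory-guided versus visually guided
    sequential reaching on a five-target touchscreen task. Provides a
    deterministic task engine for the Random (visually cued) and Repeating
    (fixed three-element sequence) task modes, a seeded generative simulator
    of reach behavior with pharmacological-injection effect scenarios
    (anisomycin, muscimol, saline), a validated tab-separated trial-log
    format, trial classification (response/movement-time derivation,
    nearest-target endpoint assignment, accuracy versus direction error
    taxonomy, predictive-response cutoff, exclusion rules), and a pre/post
    statistical pipeline (2x2 chi-square contrasts, Welch and paired t-tests,
    Holm-Bonferroni correction, strongest/weakest-movement selection and
    population aggregation across injection sessions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
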