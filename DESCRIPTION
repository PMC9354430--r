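Package: tavicea
Title: Cost-Effectiveness Modelling of Transcatheter Versus Surgical Aortic Valve Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (no stroke, stroke, death) monthly-cycle Markov
    model for the cost-effectiveness of transcatheter aortic valve
    implantation (TAVI) against surgical aortic valve replacement (SAVR) in
    severe aortic stenosis at intermediate surgical risk. Milestone
    Kaplan-Meier probabilities are converted to per-cycle transition
    probabilities, all-cause mortality is split by stroke status with
    time-since-stroke hazard ratios, and the model is evaluated either as a
    deterministic cohort trace or as a first-order microsimulation.
    Includes deterministic one-way sensitivity analysis (tornado),
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, net monetary benefit, scenario analyses, a
    synthetic-data generator for end-to-end verification, and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
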