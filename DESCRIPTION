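Package: icbtcea
Title: Cost-Effectiveness Modelling of Guided Internet-Based Versus
    In-Person Low-Intensity CBT for Mild Depression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic model of low-intensity cognitive behavioural
    therapy (CBT) delivery for university students with mild depressive
    symptoms: a short-term acceptance/compliance/response decision tree
    feeding a 60-cycle monthly Markov cohort model of remission, relapse by
    symptom severity, and all-cause death, with school dropout tracked as a
    parallel outcome.  Produces discounted costs, quality-adjusted life
    years (QALYs) and incremental cost-effectiveness ratios (ICERs) for a
    guided internet-based strategy against conventional in-person delivery,
    together with one-way, two-way and threshold deterministic sensitivity
    analyses, a Monte Carlo probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and an individual-level
    microsimulation that serves as a validation oracle for the cohort
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
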