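Package: partolab
Title: Contraction-Peak Phenotyping and Heteroscedastic Contrasts for
    Intrauterine-Pressure Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for intrauterine-pressure telemetry in mouse
    parturition studies. Resamples pressure traces to 1 Hz, detects
    contraction peaks by height and topographic prominence, summarizes labor
    events (inter-pup intervals, zeitgeber-time onset classification), and
    estimates tissue-specific knockout effects on mean peak pressure with a
    feasible generalized-least-squares model allowing group-dependent error
    variance, tested by one-sided t contrasts. Includes exact small-sample
    tests (Fisher 2x2, Mann-Whitney, Kruskal-Wallis), a rule-based classifier
    for mechanically activated patch-clamp currents (8-pole Bessel low-pass,
    baseline-window statistics, 5x-SD threshold), and a seeded synthetic-data
    generator producing cohorts with the statistical structure the pipeline
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
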