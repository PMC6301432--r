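Package: netpanel
Title: Longitudinal Name-Generator Network Panels with Respondent-Driven
    Sampling Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal egocentric (name-generator) network
    panels collected in respondent-driven sampling (RDS) cohort studies of
    hidden populations. Provides a seeded cohort simulator (two-block
    hidden population, coupon-based RDS recruitment, wave-to-wave tie
    retention and arrival, differential attrition, capped confidant and
    sexual-partner rosters with respondent-confirmed cross-wave matches),
    a validated roster data model with alter identity resolution, tie
    stability and turnover ratios with group comparisons, composite
    sociometric network metrics (degree, betweenness, component-corrected
    closeness, average shortest path length), ego-network composition
    covariates, baseline and unadjusted odds-ratio comparisons, and a
    deterministic end-to-end pipeline with delimited-text and GraphML
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
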