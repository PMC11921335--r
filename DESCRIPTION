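Package: ivoc
Title: Indoor VOC Exposure Analysis from Time-Integrated Home Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing indoor volatile organic compound (VOC)
    exposure in home cohorts sampled with time-integrated whole-air
    canisters. Infers per-home air change rates from an occupancy-driven
    carbon dioxide mass balance, treats episodic concentration outliers
    with log-scale modified Z-scores, converts indoor/outdoor
    concentration differences into time-averaged emission rates with
    min-max normalisation and class totals, benchmarks concentrations
    against inhalation unit risks (lifetime cancer risk) and reference
    concentrations (hazard quotient), and compares groups with a
    nonparametric stack (Brunner-Munzel, Kruskal-Wallis with Dunn post
    hoc, Holm correction, bootstrap percentile confidence intervals).
    Includes a seeded synthetic home-cohort generator with log-normal
    concentrations, seasonal ventilation structure, urban/rural aromatic
    shifts and episodic painting-style spikes, so the full pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
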