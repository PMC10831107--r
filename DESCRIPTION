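Package: aerohab
Title: Predictability of Aerobic Habitat Viability from the Metabolic Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute the normalized Metabolic Index (phi), a
    trait-based measure of aerobic habitat suitability, from gridded ocean
    temperature, salinity and dissolved oxygen; to verify initialized
    ensemble hindcasts of phi against a reconstruction using anomaly
    correlation and normalized mean absolute error with a persistence
    baseline, effective degrees of freedom, and dependent-correlation
    difference tests; to attribute phi variability and forecast skill to its
    oxygen, temperature and salinity drivers via a first-order Taylor
    decomposition (including the oxygen solubility / apparent oxygen
    utilization split) and a variance budget; and to sweep predictability
    across ecotype traits. A synthetic ensemble-hindcast generator with
    prescribed red-noise memory, cross-variable coupling, lead-dependent
    skill and drift provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ncdf4,
    optparse
Config/testthat/edition: 3
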