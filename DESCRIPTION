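Package: planktonbox
Title: Quota-Based Plankton Ecosystem Box and Column Model with Skill Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-dimensional box and one-dimensional column simulator for a
    pelagic biogeochemical model of an oligotrophic, river-influenced coastal
    sea. Phytoplankton and heterotrophic bacteria carry variable intracellular
    C, N and (optionally) P quotas; growth follows Droop/Geider kinetics with
    Liebig co-limitation, chlorophyll-to-carbon photoacclimation and an
    implicit, temperature-limited zooplankton closure. Two nested model
    versions are provided: a 12-variable C/N configuration and a 17-variable
    C/N/P configuration. The package also builds boundary forcing from river,
    wastewater and atmospheric-deposition records (labile-fraction rules,
    constant-source tables), generates synthetic seasonal, upwelling and
    river-intrusion scenarios, and computes model-observation skill statistics
    (percentage bias, cost function with OSPAR rating, average absolute error,
    RMSD, correlation and normalized target-diagram coordinates).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
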