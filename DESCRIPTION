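Package: edempflux
Title: Carbon Flux Analysis of Engineered Xylose Metabolism in Pseudomonas putida
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 13C metabolic flux analysis (MFA) and constraint-based
    modelling of the xylose-assimilating EDEMP cycle of engineered Pseudomonas
    putida. Implements atom-mapped core-network parsing, forward simulation of
    mass isotopomer distributions (MIDs) by elementary metabolite unit (EMU)
    decomposition with an exhaustive isotopomer oracle, correction of measured
    MIDs for natural isotope abundance and unlabelled inoculum biomass,
    weighted least-squares flux estimation with chi-square goodness of fit and
    parameter-continuation confidence intervals, genome-scale flux balance
    analysis with MFA-derived flux bounds and cofactor/CO2 accounting, and
    growth-kinetics estimation (maximum specific growth rate, lag, biomass
    yield, specific substrate uptake) from OD600 time series. Ships an
    atom-mapped EDEMP + xylose-isomerase core network and synthetic-data
    generators for MID datasets and growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
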