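Package: plastclim
Title: Optimality Models of Transgenerational Plasticity Under Climatic
    Autocorrelation
Version: 0.1.0
Authors@R:
    person("Plastclim", "Developers", email = "plastclim@example.org",
           role = c("aut", "cre"))
Description: Tools to study when transgenerational phenotypic plasticity is
    favoured by the interannual autocorrelation structure of climate.  The
    package aggregates monthly precipitation and growing-season temperature
    records into annual series (hydrologic-year totals, early/late season
    means), computes descriptive statistics (interannual standard deviation,
    linear trends, autocorrelations and partial autocorrelations up to lag
    12, seasonal cross-correlations), and grid-searches plasticity
    "genotypes" for the strategy maximising geometric-mean fitness at each
    site, in raw and linearly detrended variants.  A seeded synthetic
    climate generator with controlled AR(p) / VAR(1) structure stands in
    for gridded observational data, and a small command-line interface
    batches the pipeline over many sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
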