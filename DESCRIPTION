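Package: dspom
Title: Dynamic Stochastic Patch Occupancy Models for Hydrologically
    Fluctuating Wetlandscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates metapopulation occupancy dynamics in patchy aquatic
    habitats whose suitability and connectivity fluctuate with hydroclimatic
    forcing. Couples a parsimonious per-wetland water balance (power-law
    stage-area bathymetry, marked-Poisson rainfall, Thornthwaite potential
    evapotranspiration) to a discrete-time stochastic patch occupancy Markov
    chain (SPOM) with time-varying suitability and perimeter-to-perimeter gap
    distances. Computes time-resolved metapopulation capacity (the leading
    eigenvalue of the landscape matrix), Monte-Carlo occupancy and survival
    statistics, emergent dispersal-network topology (degree, betweenness,
    network length) and network length duration curves, and runs independent
    chains for species with shallow, intermediate and deep water-depth niche
    preferences. Includes generators for synthetic wetlandscapes emulating
    dense/heterogeneous and sparse/homogeneous archetypes, plus a
    configuration-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
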