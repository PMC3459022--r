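Package: enzcomm
Title: Individual-Based Simulation of Exoenzyme-Producing Microbial
    Communities and Join-Count Spatial Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-genotype, multi-nutrient individual-based model of
    exoenzyme-producing microbes on a 2-D lattice. Eight genotypes differing
    at three enzyme-production loci (carbon, nitrogen, phosphorus) compete
    for polymeric substrates that must be hydrolyzed by diffusible
    extracellular enzymes, making enzymes a public good open to cheating.
    The package provides the per-minute simulation engine (substrate input,
    decay, stochastic pairwise diffusion, Michaelis-Menten product formation
    and uptake, stoichiometrically constrained enzyme production, division,
    mutation, and mortality), community metrics (genotype densities, Simpson
    diversity, nutrient depolymerization), and a spatial-statistics toolkit:
    temporal-independence sampling of raster snapshots, multi-category
    join-count z-statistics under the Cliff-Ord nonfree-sampling null at
    multiple neighborhood radii, chi-square aggregation with Bonferroni
    correction, association scores, and the correlation of association
    strength with genotype complementation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
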