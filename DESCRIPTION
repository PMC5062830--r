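Package: coalsel
Title: Demographic Scenario Selection by Structured Coalescent Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-based testing of competing demographic hypotheses for
    phylogeographic data. Simulates genealogies under structured serial
    coalescent scenarios (deme growth, backward migration into a source deme,
    deme extinction), evolves nucleotide alignments on them under HKY or TIM1
    substitution models with discrete-gamma rate heterogeneity, computes
    haplotype and nucleotide diversity, and ranks scenarios against observed
    statistics by two-tailed simulation probabilities, empirical
    log-likelihoods and Akaike weights. Also provides AMOVA phiST, Mantel
    tests of isolation by distance, palaeo-suitability stability and range
    centroid analyses, and quantile regressions of diversity on suitability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    geosphere,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
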