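Package: sparsecross
Title: Stochastic Simulation of Sparse Testcrossing in Hybrid Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of reciprocal recurrent
    genomic selection in a two-pool hybrid breeding program, built to study
    sparse testcrossing designs for early-stage genomic prediction of general
    combining ability (GCA). Simulates founder genomes with linkage
    disequilibrium, quantitative traits with directional dominance and
    overdominance, doubled-haploid line development, testcross mating designs
    with one to many testers, ridge-regression BLUP marker-effect models
    (including a heterotic-pool-specific additive + dominance model), and
    ground-truth population metrics such as GCA/SCA variance components,
    Nei's minimum genetic distance, mid-parent heterosis and hybrid genetic
    gain over breeding cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
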