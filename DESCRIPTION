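Package: paleorange
Title: Time-Stratified Historical Biogeography and Latitudinal Evolution with Fossil Tips
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Dispersal-extinction-cladogenesis (DEC) inference of ancestral
    geographic ranges on time-calibrated phylogenies that include fossil tips,
    under a time-stratified geographic model in which area connectivity changes
    across geological time slices. Provides maximum-likelihood estimation of
    dispersal and extirpation rates, ranked marginal ancestral-range estimates,
    extraction and dating of biogeographic events (dispersals into and out of
    regions, extirpations, vicariance), and a Markov chain Monte Carlo
    reconstruction of a clade's latitudinal span through time under Brownian
    motion with a piecewise directional trend, using extant latitudes and
    fossil paleolatitudes. Includes forward simulators (fossilized birth-death
    trees, DEC range histories, trended Brownian latitudes) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
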