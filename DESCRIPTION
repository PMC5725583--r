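Package: recstorage
Title: Evolution of Recombination under the Genomic Storage Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a three-locus haploid model of the
    genomic storage effect in periodic environments: a seasonally selected
    target locus, an epistatic phenotypic-plasticity modifier that buffers the
    seasonal fitness effect, and a recombination modifier controlling the rate
    of recombination between them. Provides the deterministic haplotype
    recursion (selection plus a mechanistic crossover operator), local
    stability analysis of periodic orbits via cycle Jacobians, pairwise
    invasion analysis of recombination-rate alleles and the evolutionarily
    stable recombination rate, Wright-Fisher finite-population engines
    (multinomial haplotype sampling and an individual-based engine with a
    continuum of recombination-rate alleles under recurrent mutation), and
    multilocus protocols for the clustering of co-modulated target loci into
    supergenes. Diagnostics include cycling linkage disequilibrium, the sign
    of epistasis, and geometric-mean relative fitness of modifier alleles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
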