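Package: bgsmap
Title: Quantitative-Genetic Background Selection Maps and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Solves the Santiago-Caballero (SC16) equilibrium system coupling
    additive fitness variance, the deleterious substitution rate and the
    fitness-effective population size for conserved genomic segments; builds
    genome-wide diversity-reduction maps (the B' maps, with the classic
    background-selection B map as the strong-selection special case); fits the
    per-feature distribution of fitness effects, deleterious mutation rate and
    baseline diversity to windowed pairwise diversity by composite likelihood
    (BOBYQA with softmax-parameterised DFE columns, leave-one-chromosome-out
    cross-validation and block jackknife); predicts deleterious substitution
    rates and implied divergence; and validates the theory with a built-in
    Wright-Fisher forward simulator and synthetic-genome generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    jsonlite,
    minqa,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
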