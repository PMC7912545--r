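Package: peddiv
Title: Pedigree-Based Genetic Diversity, Population Structure and Breed
    Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genetic diversity and population structure
    from studbook pedigrees, with composite (multi-breed) populations in
    mind. Computes pedigree completeness, generation numbers and intervals,
    inbreeding by the Meuwissen-Luo algorithm, average relatedness and mean
    coancestries through indirect relationship-matrix products, individual
    rates of inbreeding and coancestry, realized effective population sizes,
    probabilities of gene origin (effective numbers of founders, ancestors
    and founder genomes, gene dropping), Wright's fixation indices, Nei
    minimum distances with UPGMA trees, and a canonical discriminant
    analysis of per-individual diversity parameters with leave-one-out
    cross-validation and Press' Q. Includes a seeded synthetic-pedigree
    generator that emulates the formation of a composite breed from two
    purebred base populations, so every stage of the pipeline can be
    exercised and tested without restricted studbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
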