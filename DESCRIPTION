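Package: cucumap
Title: Consensus Genetic Map Integration and NB-LRR Resistance Gene
    Homolog Analysis for Cucurbit Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building genetic linkage maps from F2 and
    recombinant-inbred-line genotype data (EM recombination-fraction
    estimation, LOD scores, Kosambi and Haldane map functions, marker
    ordering by sum of adjacent recombination fractions), integrating
    multiple component maps into a consensus map with a 1-cM bin-mapping
    strategy (bin construction, bridge-marker selection, chromosome
    conflict resolution, LOD-weighted recombination pooling, residual
    refill), and characterising nucleotide-binding leucine-rich-repeat
    (NB-LRR) resistance gene homologs (domain-architecture
    classification, physical cluster detection, neighbor-joining NB
    phylogeny with bootstrap, EST support and ortholog calls), together
    with in silico PCR scaffold anchoring and genetic-physical
    colinearity statistics. A seeded synthetic-data generator emulates
    segregating cucumber populations and draft-genome scaffolds so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
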