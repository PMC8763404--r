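Package: gutbridge
Title: Translating Gut-Microbiota Functions Between Host Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and comparing genome-resolved gut microbiota
    catalogs across host species. Implements genome quality scoring and
    tiering from CheckM-style summaries, bottom-s MinHash sketching with
    Mash-distance estimation for dereplication and average-nucleotide-identity
    species clustering, pangenome functional profiling as per-species
    genome-carrying feature fractions, taxonomic (cophenetic) versus
    functional (Jaccard) distance mapping to identify functionally equivalent
    species between two host catalogs, Smith-Waterman protein catalog search
    with percent-identity cutoffs for gene localization (for example drug
    metabolism genes and butyrate terminal pathway genes), compositional
    analysis of species abundance tables (centered log-ratio, Aitchison
    distance, prevalence), and seeded synthetic-data generators that emit
    every input format the pipeline consumes together with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
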