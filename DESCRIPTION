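Package: genehood
Title: Genomic Neighborhood Enrichment Analysis of Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein domains statistically overrepresented in the
    genomic neighborhoods of a query domain (or gene list) across large
    collections of annotated bacterial genomes. Neighborhoods are the genes
    within a fixed base-pair radius of each query gene on its contig; target
    domain counts are scored with an upper-tail Poisson probability whose
    expectation is calibrated against whole-database domain frequencies.
    Includes an optional subtaxon resampling step that equalizes the
    contribution of taxa to correct for uneven genome sampling, Jaccard-index
    single-linkage clustering of neighborhoods by domain composition, mapping
    of significant domains to Gene Ontology terms, and a seeded synthetic
    genome-annotation simulator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
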