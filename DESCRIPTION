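Package: proteoPGLS
Title: Phylogenetic Regression of Proteome Amino Acid Composition on
    Ecological Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether proteome amino-acid composition
    covaries with ecological traits across a phylogeny. Computes
    codon-redundancy-standardized, cross-species-normalised amino-acid
    profiles from protein FASTA files (whole proteome and
    orthologous/non-orthologous gene partitions), derives genus-level
    diet breadth from host-plant records and realised thermal maxima
    from occurrence points over a bioclimatic grid, and fits a
    phylogenetic generalized least squares model per amino acid under
    Brownian-motion covariance, repeated across an ensemble of tree
    topologies with Benjamini-Hochberg correction. A synthetic-data
    generator with known ground truth exercises every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Proteomics, Regression, Software
RoxygenNote: 7.3.3
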