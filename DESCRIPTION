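Package: metacascade
Title: Iterative Generalist-Database Metaproteomics for Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing the microbiome of a host organism
    without a sequenced genome from tandem mass-spectrometry data, using an
    iterative (cascade) database-search strategy. Starting from validated
    peptide-spectrum matches, the package infers taxa with a controlled
    taxonomic false-discovery rate, tailors sample-specific protein
    sub-databases (host, food, unicellular), quantifies relative biomass from
    taxon-specific spectrum counts, performs parsimony-based protein-group
    inference with spectral counting, rolls microbial abundances up to GOslim
    functional categories, and runs between-tissue differential statistics
    (total-sum scaling, exact Wilcoxon tests with Benjamini-Hochberg
    correction, Bray-Curtis dissimilarities). A synthetic-fixture generator
    produces self-contained toy worlds with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
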