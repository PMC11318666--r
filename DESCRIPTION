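Package: evrc
Title: Chromosome 3D Structure Reconstruction by Co-Clustering-Weighted
    Error-Vector Resultants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs 3D chromosome and genome structure models from
    chromatin interaction (Hi-C style) frequency matrices. Interaction
    frequencies are converted to target spatial distances by a power law,
    each pair of genomic bins is weighted by its co-clustering coefficient
    in the contact graph, and bin coordinates are refined iteratively by
    adding the weighted resultant of per-pair error vectors until the
    objective stabilises. Handles single chromosomes and multi-chromosome
    assemblies (intra- plus inter-chromosome matrices), includes a
    simulation test bed of six canonical curve structures with a
    multiplicative distance-noise model, and provides evaluation metrics
    (superposition RMSD, distance Pearson correlation, and Spearman
    correlation of recovered contact frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    bio3d
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
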