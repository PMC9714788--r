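Package: osteomsi
Title: Spatial Metabolomics Analysis of MALDI Mass Spectrometry Imaging of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for MALDI mass spectrometry
    imaging (MSI) of undecalcified bone sections: imzML input/output,
    root-mean-square spectrum normalization, mean-spectrum peak picking with a
    robust noise model, ion-image data cubes, probabilistic latent semantic
    analysis (pLSA) and PCA tissue segmentation, adduct-aware accurate-mass
    metabolite annotation against a bundled reference table, compositional
    glycan-fragment annotation, region-of-interest differential statistics
    (Mann-Whitney, Kruskal-Wallis with Dunn's post hoc test and
    Benjamini-Hochberg correction), hypergeometric pathway enrichment, and
    spatial Spearman-correlation pathway networks. A ground-truthed synthetic
    bone-phantom generator (cortical ring, osteoid seam, marrow core; two
    genotype groups with planted effects) makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    xml2,
    igraph,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
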