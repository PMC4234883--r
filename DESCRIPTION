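Package: voxtome
Title: Spatially Resolved Transcriptome Imaging of Microdissected Tissue Voxels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide transcriptional imaging of laser-microdissected tissue
    voxels sampled on a regular 50 micrometre grid. Provides per-million
    normalization of voxel count matrices, Mapper-style topological clustering
    (norm-correlation metric, metric-SVD lenses, equalized covers with gain
    overlap, nerve graph, modularity segmentation), spatial back-projection of
    gene expression and cluster labels onto the section grid, per-cluster
    marker detection by Kolmogorov-Smirnov testing with Bonferroni control,
    and a seeded synthetic voxel-data generator with planted spatial programs
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
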