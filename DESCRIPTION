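Package: mutumap
Title: UMAP Visualization and Clustering of Single-Cell Somatic Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-cell ANNOVAR-annotated somatic single-nucleotide
    variant tables plus a sample metadata file into a genes-by-cells
    mutation-count matrix stored in the AnnData on-disk convention, applies a
    five-step quality-control and normalization chain (gene/cell support
    filters, upper-percentile outlier removal, median-target normalization with
    logarithmization, highly-variable-gene selection and regressing out
    per-cell total counts), embeds cells in two dimensions with UMAP, assigns
    Leiden and Louvain cluster labels, and produces QC plots, UMAP plots,
    per-patient summary reports and group-level mutated-gene Venn analytics.
    Includes a synthetic-data generator with planted group structure for
    testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    rhdf5,
    uwot,
    RANN,
    irlba,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
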