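#' Pipeline configuration
#'
#' Collects every tunable threshold and seed of the pipeline in one validated
#' list, so that a run can be reproduced from its serialized configuration.
#' Defaults are the pipeline's published values: genes must be mutated in at
#' least 3 cells, cells must carry at least 30 mutated genes, cells above the
#' 98th percentile of mutated-gene counts are dropped as outliers, counts are
#' normalized to the median per-cell total and log-transformed, and the top
#' 3000 highly variable genes are retained before regressing out per-cell
#' totals.
#'
#' @param min_cells_per_gene Genes mutated in fewer than this many cells are
#'   removed (default 3).
#' @param min_genes_per_cell Cells with fewer than this many mutated genes are
#'   removed (default 30).
#' @param upper_percentile Cells whose mutated-gene count strictly exceeds this
#'   percentile (linear interpolation over currently retained cells) are
#'   removed; in (0, 100], default 98.
#' @param n_hvg Number of highly variable genes to keep (default 3000).
#' @param target_sum Per-cell total after normalization; a positive number or
#'   `"median"` (the median of pre-normalization per-cell totals, the default).
#' @param n_pcs Number of principal components (default 50; capped below the
#'   matrix rank at run time).
#' @param n_neighbors Size of the kNN neighborhood for the cell graph
#'   (default 15).
#' @param resolution Resolution parameter passed to Leiden/Louvain
#'   (default 1).
#' @param seed Integer seed driving PCA initialization, the UMAP layout and
#'   graph clustering (default 0).
#' @param keep_classes Functional classes of variants retained before
#'   counting; default `"nonsynonymous SNV"`. Use [functional_classes()] for
#'   the full vocabulary, or `keep_classes = functional_classes()` to keep
#'   everything.
#' @param scale_before_pca If `TRUE`, unit-variance scale genes after the
#'   regress-out step and before PCA. Off by default: the published chain
#'   lists no scaling step.
#' @param percentile_before_min_genes If `TRUE`, compute the upper-percentile
#'   cut before (rather than after) the minimum-genes-per-cell filter.
#' @param malformed_tolerance Maximum tolerated fraction of malformed rows per
#'   annotation file before parsing errors out (default 0.2).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cells_per_gene = 3L,
                            min_genes_per_cell = 30L,
                            upper_percentile = 98,
                            n_hvg = 3000L,
                            target_sum = "median",
                            n_pcs = 50L,
                            n_neighbors = 15L,
                            resolution = 1,
                            seed = 0L,
                            keep_classes = "nonsynonymous SNV",
                            scale_before_pca = FALSE,
                            percentile_before_min_genes = FALSE,
                            malformed_tolerance = 0.2) {
  stopifnot(
    min_cells_per_gene >= 1, min_genes_per_cell >= 1,
    upper_percentile > 0, upper_percentile <= 100,
    n_hvg >= 1, n_pcs >= 2, n_neighbors >= 2, resolution > 0,
    malformed_tolerance >= 0, malformed_tolerance <= 1,
    length(keep_classes) >= 1
  )
  if (!identical(target_sum, "median")) {
    stopifnot(is.numeric(target_sum), length(target_sum) == 1, target_sum > 0)
  }
  cfg <- list(
    min_cells_per_gene = as.integer(min_cells_per_gene),
    min_genes_per_cell = as.integer(min_genes_per_cell),
    upper_percentile = as.numeric(upper_percentile),
    n_hvg = as.integer(n_hvg),
    target_sum = target_sum,
    n_pcs = as.integer(n_pcs),
    n_neighbors = as.integer(n_neighbors),
    resolution = as.numeric(resolution),
    seed = as.integer(seed),
    keep_classes = as.character(keep_classes),
    scale_before_pca = isTRUE(scale_before_pca),
    percentile_before_min_genes = isTRUE(percentile_before_min_genes),
    malformed_tolerance = as.numeric(malformed_tolerance)
  )
  structure(cfg, class = "pipeline_config")
}

#' Closed vocabulary of ANNOVAR exonic functional classes
#'
#' Classes outside this vocabulary are mapped to `"other"` at parse time so
#' every record carries a recognized class.
#'
#' @return Character vector of functional-class names.
#' @export
functional_classes <- function() {
  c(
    "nonsynonymous SNV", "synonymous SNV", "stopgain", "stoploss",
    "startloss", "unknown",
    "frameshift insertion", "frameshift deletion",
    "nonframeshift insertion", "nonframeshift deletion",
    "frameshift substitution", "nonframeshift substitution",
    "other"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
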