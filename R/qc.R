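#' @name qc_filters
#' @rdname qc_filters
#' @title Sequential QC filters on the mutation-count matrix
#'
#' @description
#' The three filtering steps of the preprocessing chain, applied in printed
#' order and exactly once each:
#' \enumerate{
#'   \item [filter_genes_min_cells()] removes genes mutated in fewer than
#'     `k` cells (default 3);
#'   \item [filter_cells_min_genes()] removes cells with fewer than `k`
#'     mutated genes (default 30; "fewer than 30" excluded, so 30 is kept);
#'   \item [filter_cells_upper_percentile()] removes outlier cells whose
#'     mutated-gene count strictly exceeds the `p`-th percentile (linear
#'     interpolation, default 98) of the currently retained cells.
#' }
#' Each returns the filtered `mutation_matrix` with attribute `removed`
#' (labels of dropped cells or genes).
#'
#' @param m A `mutation_matrix`.
#' @param k Integer threshold (minimum cells per gene, or genes per cell).
#' @param p Percentile in (0, 100].
NULL

#' @rdname qc_filters
#' @export
filter_genes_min_cells <- function(m, k = 3L) {
  stopifnot(inherits(m, "mutation_matrix"), k >= 1)
  support <- Matrix::colSums(m$counts > 0)
  keep <- support >= k
  if (!any(keep)) {
    stop("all genes filtered: no gene is mutated in at least ", k, " cells")
  }
  out <- subset_matrix(m, genes = which(keep))
  attr(out, "removed") <- colnames(m$counts)[!keep]
  out
}

#' @rdname qc_filters
#' @export
filter_cells_min_genes <- function(m, k = 30L) {
  stopifnot(inherits(m, "mutation_matrix"), k >= 1)
  n_genes <- Matrix::rowSums(m$counts > 0)
  keep <- n_genes >= k
  if (!any(keep)) {
    stop("all cells filtered: no cell has at least ", k, " mutated genes")
  }
  out <- subset_matrix(m, cells = which(keep))
  attr(out, "removed") <- rownames(m$counts)[!keep]
  out
}

#' @rdname qc_filters
#' @export
filter_cells_upper_percentile <- function(m, p = 98) {
  stopifnot(inherits(m, "mutation_matrix"), p > 0, p <= 100)
  n_genes <- Matrix::rowSums(m$counts > 0)
  if (length(n_genes) < 2) {
    out <- m
    attr(out, "removed") <- character(0)
    attr(out, "threshold") <- unname(max(n_genes))
    return(out)
  }
  t <- unname(stats::quantile(n_genes, p / 100, type = 7))
  keep <- n_genes <= t
  out <- subset_matrix(m, cells = which(keep))
  attr(out, "removed") <- rownames(m$counts)[!keep]
  attr(out, "threshold") <- t
  out
}

#' Normalize each cell's counts to a common total
#'
#' Scales every cell so its total equals `target_sum`; with the default
#' `"median"`, the target is the median of pre-normalization per-cell totals,
#' so the typical cell is left nearly unchanged.
#'
#' @param m A `mutation_matrix` with no all-zero cells.
#' @param target_sum Positive number or `"median"`.
#' @return A list: `values` (dgCMatrix of normalized reals, cells x genes),
#'   `totals` (pre-normalization per-cell totals), `target` (the target used).
#' @export
normalize_total <- function(m, target_sum = "median") {
  stopifnot(inherits(m, "mutation_matrix"))
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0)) {
    stop("internal invariant violation: all-zero cell reached normalization")
  }
  target <- if (identical(target_sum, "median")) {
    stats::median(totals)
  } else {
    as.numeric(target_sum)
  }
  values <- Matrix::Diagonal(x = target / totals) %*% m$counts
  dimnames(values) <- dimnames(m$counts)
  list(values = methods::as(values, "CsparseMatrix"),
       totals = totals, target = target)
}

#' Elementwise log(1 + x) transform
#'
#' @param values Non-negative matrix (sparse or dense).
#' @return Matrix of the same shape with `log1p` applied; zero maps to zero
#'   so sparsity is preserved.
#' @export
log1p_transform <- function(values) {
  if (methods::is(values, "sparseMatrix")) {
    v <- methods::as(values, "CsparseMatrix")
    if (any(v@x < 0)) stop("log1p requires non-negative values")
    v@x <- log1p(v@x)
    v
  } else {
    if (any(values < 0)) stop("log1p requires non-negative values")
    log1p(values)
  }
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Per gene, mean and dispersion (variance/mean) are computed on the
#' `expm1` scale of the log-normalized values, following the Seurat-flavour
#' convention. Genes are then assigned to 20 equal-count bins of mean, the
#' dispersion is z-scored within each bin, and the top `n` genes by
#' normalized dispersion are selected (ties broken by the stable input gene
#' order). Bins with a single gene, or zero within-bin spread, get a
#' normalized dispersion of 0.
#'
#' @param values Log-normalized matrix, cells x genes.
#' @param n Number of genes to select (capped at the number of genes).
#' @param n_bins Number of mean bins (default 20).
#' @return A list: `genes` (selected gene names, stable input order),
#'   `table` (per-gene tibble: gene_id, mean, dispersion, dispersion_norm,
#'   bin, selected).
#' @export
select_hvg <- function(values, n = 3000L, n_bins = 20L) {
  stopifnot(n >= 1)
  if (ncol(values) < 2) stop("need at least 2 genes for HVG selection")
  x <- expm1_matrix(values)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(square_matrix(x))
  n_cells <- nrow(x)
  v <- (ex2 - mu^2) * n_cells / max(1, n_cells - 1)
  disp <- ifelse(mu > 0, v / mu, 0)

  # equal-count mean bins
  n_bins <- min(n_bins, length(mu))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  bin <- if (length(br) < 2) {
    rep(1L, length(mu)) # all means identical: a single bin
  } else {
    cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  disp_norm <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- which(bin == b)
    if (length(i) < 2) {
      disp_norm[i] <- 0
      next
    }
    s <- stats::sd(disp[i])
    disp_norm[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  k <- min(n, length(disp_norm))
  ord <- order(-disp_norm) # ties keep input order (stable radix sort)
  sel <- sort(ord[seq_len(k)])
  tbl <- tibble::tibble(
    gene_id = colnames(values),
    mean = unname(mu),
    dispersion = unname(disp),
    dispersion_norm = unname(disp_norm),
    bin = as.integer(bin),
    selected = seq_along(mu) %in% sel
  )
  list(genes = colnames(values)[sel], table = tbl)
}

expm1_matrix <- function(values) {
  if (methods::is(values, "sparseMatrix")) {
    v <- methods::as(values, "CsparseMatrix")
    v@x <- expm1(v@x)
    v
  } else {
    expm1(values)
  }
}

square_matrix <- function(values) {
  if (methods::is(values, "sparseMatrix")) {
    v <- methods::as(values, "CsparseMatrix")
    v@x <- v@x^2
    v
  } else {
    values^2
  }
}

#' Regress out per-cell total counts
#'
#' Replaces each gene's values by the residuals of an ordinary-least-squares
#' fit on (intercept, per-cell total counts), removing the linear effect of
#' mutational burden. After this step every gene's residuals are numerically
#' orthogonal to the covariate.
#'
#' @param values Matrix, cells x genes (dense result).
#' @param totals Strictly positive per-cell covariate, length `nrow(values)`.
#' @return Dense matrix of residuals with the input dimnames.
#' @export
regress_out_total <- function(values, totals) {
  values <- as.matrix(values)
  stopifnot(length(totals) == nrow(values), all(totals > 0))
  if (stats::sd(totals) == 0) {
    warning("constant covariate: regression undefined up to intercept; skipped")
    return(values)
  }
  design <- cbind(1, totals)
  # residuals = Y - X (X'X)^-1 X'Y, one solve shared across all genes
  coef <- solve(crossprod(design), crossprod(design, values))
  res <- values - design %*% coef
  dimnames(res) <- dimnames(values)
  res
}

#' Run the five-step preprocessing chain
#'
#' Applies, in order: (1) the minimum-cells-per-gene filter, (2) the
#' minimum-genes-per-cell filter, (3) the upper-percentile outlier cut,
#' (4) median-target normalization followed by log1p, and (5) highly variable
#' gene selection followed by regressing out per-cell total counts. Returns
#' everything downstream steps and reports need.
#'
#' @param m A `mutation_matrix` from [ingest_variants()] or [read_matrix()].
#' @param config A [pipeline_config()].
#' @return A list of class `qc_result`: `matrix` (post-filter count
#'   `mutation_matrix`), `values` (dense processed matrix, cells x HVG),
#'   `totals` (per-cell totals used for normalization and regress-out),
#'   `target`, `hvg` (the [select_hvg()] table), `report` (a `filter_report`
#'   tibble), `config`.
#' @export
qc_preprocess <- function(m, config = pipeline_config()) {
  stopifnot(inherits(m, "mutation_matrix"))
  steps <- list()
  note_step <- function(name, before, after, removed, threshold = NA_real_) {
    tibble::tibble(
      step = name,
      n_cells_before = nrow(before$counts), n_cells_after = nrow(after$counts),
      n_genes_before = ncol(before$counts), n_genes_after = ncol(after$counts),
      threshold = threshold,
      removed = list(removed)
    )
  }

  m1 <- filter_genes_min_cells(m, config$min_cells_per_gene)
  steps$genes_min_cells <- note_step(
    "filter_genes_min_cells", m, m1, attr(m1, "removed"),
    config$min_cells_per_gene
  )

  if (config$percentile_before_min_genes) {
    m2a <- filter_cells_upper_percentile(m1, config$upper_percentile)
    steps$upper <- note_step(
      "filter_cells_upper_percentile", m1, m2a, attr(m2a, "removed"),
      attr(m2a, "threshold")
    )
    m2 <- filter_cells_min_genes(m2a, config$min_genes_per_cell)
    steps$min_genes <- note_step(
      "filter_cells_min_genes", m2a, m2, attr(m2, "removed"),
      config$min_genes_per_cell
    )
    m3 <- m2
  } else {
    m2 <- filter_cells_min_genes(m1, config$min_genes_per_cell)
    steps$min_genes <- note_step(
      "filter_cells_min_genes", m1, m2, attr(m2, "removed"),
      config$min_genes_per_cell
    )
    m3 <- filter_cells_upper_percentile(m2, config$upper_percentile)
    steps$upper <- note_step(
      "filter_cells_upper_percentile", m2, m3, attr(m3, "removed"),
      attr(m3, "threshold")
    )
  }

  norm <- normalize_total(m3, config$target_sum)
  logged <- log1p_transform(norm$values)
  hvg <- select_hvg(logged, config$n_hvg)
  values <- as.matrix(logged[, hvg$genes, drop = FALSE])
  values <- regress_out_total(values, norm$totals)
  if (config$scale_before_pca) {
    sds <- apply(values, 2, stats::sd)
    sds[sds == 0] <- 1
    values <- scale(values, center = TRUE, scale = sds)
    values <- values[, , drop = FALSE]
    attr(values, "scaled:center") <- NULL
    attr(values, "scaled:scale") <- NULL
  }

  report <- dplyr::bind_rows(steps)
  class(report) <- c("filter_report", class(report))
  structure(list(
    matrix = m3, values = values, totals = norm$totals, target = norm$target,
    hvg = hvg$table, report = report, config = config
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  cat(sprintf("  post-filter: %d cells x %d genes; %d HVG; target sum %.6g\n",
              nrow(x$matrix$counts), ncol(x$matrix$counts),
              ncol(x$values), x$target))
  print(glance(x))
  invisible(x)
}

#' Tidy method for QC results: the per-step filter report
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return The filter report tibble (one row per step with before/after cell
#'   and gene counts, the threshold applied and removed labels).
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$matrix$counts),
    n_genes = ncol(x$matrix$counts),
    n_hvg = ncol(x$values),
    target_sum = x$target,
    mean_mutations_per_cell = mean(x$totals)
  )
}

#' Write a filter report as TSV and JSON
#'
#' @param report A `filter_report` tibble (from `tidy(qc_result)`).
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Paths written, invisibly.
#' @export
write_filter_report <- function(report, path_prefix) {
  flat <- dplyr::mutate(
    report,
    n_removed = lengths(.data$removed),
    removed = purrr::map_chr(.data$removed, paste, collapse = ",")
  )
  tsv <- paste0(path_prefix, ".tsv")
  readr::write_tsv(flat, tsv)
  json <- paste0(path_prefix, ".json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, json))
}
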