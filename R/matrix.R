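#' A cells-by-genes mutation-count container
#'
#' Pairs a sparse non-negative integer count matrix (cells in rows, genes in
#' columns) with a per-cell annotation table (`obs`) and a per-gene table
#' (`var`), mirroring the AnnData triplet. Most pipeline verbs take and return
#' this object so calls chain with the pipe.
#'
#' @param counts Matrix-like, cells x genes, non-negative integers; dimnames
#'   required and unique.
#' @param obs Data frame of per-cell annotations, one row per cell, aligned to
#'   `rownames(counts)`; a `cell_id` column is added/overwritten from the row
#'   names.
#' @param var Optional per-gene data frame aligned to `colnames(counts)`.
#'
#' @return An object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(counts, obs = NULL, var = NULL) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("empty matrix: a mutation_matrix needs at least one cell and one gene")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have cell row names and gene column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids in counts")
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("counts must be non-negative")
  if (any(m@x != round(m@x))) stop("counts must be integral")
  if (is.null(obs)) {
    obs <- tibble::tibble(cell_id = rownames(m))
  } else {
    obs <- tibble::as_tibble(obs)
    if (nrow(obs) != nrow(m)) stop("obs must have one row per cell")
    obs$cell_id <- rownames(m)
    obs <- dplyr::relocate(obs, "cell_id")
  }
  if (is.null(var)) {
    var <- tibble::tibble(gene_id = colnames(m))
  } else {
    var <- tibble::as_tibble(var)
    if (nrow(var) != ncol(m)) stop("var must have one row per gene")
    var$gene_id <- colnames(m)
    var <- dplyr::relocate(var, "gene_id")
  }
  structure(list(counts = m, obs = obs, var = var), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf(
    "<mutation_matrix> %d cells x %d genes, %d nonzero entries\n",
    nrow(x$counts), ncol(x$counts), Matrix::nnzero(x$counts)
  ))
  extra <- setdiff(names(x$obs), "cell_id")
  if (length(extra)) cat("  obs columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mutation_matrix <- function(x) dim(x$counts)

#' Cell and gene ids of a mutation matrix
#' @param m A `mutation_matrix`.
#' @return Character vector of ids.
#' @export
cell_ids <- function(m) rownames(m$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$counts)

subset_matrix <- function(m, cells = NULL, genes = NULL) {
  counts <- m$counts
  obs <- m$obs
  var <- m$var
  if (!is.null(cells)) {
    keep <- if (is.character(cells)) match(cells, rownames(counts)) else cells
    counts <- counts[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
  }
  if (!is.null(genes)) {
    keep <- if (is.character(genes)) match(genes, colnames(counts)) else genes
    counts <- counts[, keep, drop = FALSE]
    var <- var[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no cells left after subsetting")
  if (ncol(counts) == 0) stop("no genes left after subsetting")
  structure(list(counts = counts, obs = obs, var = var),
            class = "mutation_matrix")
}

#' Tidy a mutation matrix into a long tibble
#'
#' One row per nonzero (cell, gene) entry, joined with the per-cell
#' annotations.
#'
#' @param x A `mutation_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `gene_id`, `n_mutations` and the
#'   obs columns.
#' @method tidy mutation_matrix
#' @export
tidy.mutation_matrix <- function(x, ...) {
  tm <- Matrix::summary(x$counts)
  out <- tibble::tibble(
    cell_id = rownames(x$counts)[tm$i],
    gene_id = colnames(x$counts)[tm$j],
    n_mutations = as.integer(tm$x)
  )
  out <- dplyr::left_join(out, x$obs, by = "cell_id")
  dplyr::arrange(out, .data$cell_id, .data$gene_id)
}

#' One-row summary of a mutation matrix
#'
#' @param x A `mutation_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: cell/gene counts, total mutations, median
#'   mutated genes per cell.
#' @method glance mutation_matrix
#' @export
glance.mutation_matrix <- function(x, ...) {
  gpc <- Matrix::rowSums(x$counts > 0)
  tibble::tibble(
    n_cells = nrow(x$counts),
    n_genes = ncol(x$counts),
    total_mutations = sum(x$counts),
    median_genes_per_cell = stats::median(gpc),
    mean_mutations_per_cell = mean(Matrix::rowSums(x$counts))
  )
}

# ---- AnnData-convention HDF5 serialization -----------------------------------

h5_write_attr <- function(file, obj, name, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  rhdf5::h5writeAttribute(value, oid, name, variableLengthString = TRUE,
                          asScalar = length(value) == 1L)
}

# rhdf5's h5writeAttribute rejects zero-length values; write an empty
# variable-length string attribute through the low-level interface instead
h5_write_empty_string_attr <- function(file, obj, name) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  tid <- rhdf5::H5Tcopy("H5T_C_S1")
  rhdf5::H5Tset_size(tid, NULL)
  rhdf5::H5Tset_cset(tid, "UTF8")
  sid <- rhdf5::H5Screate_simple(0)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE)
  aid <- rhdf5::H5Acreate(oid, name, tid, sid)
  rhdf5::H5Aclose(aid)
  invisible(NULL)
}

h5_write_dataframe <- function(file, group, df, index_col) {
  rhdf5::h5createGroup(file, group)
  idx <- as.character(df[[index_col]])
  rhdf5::h5write(idx, file, paste0(group, "/", index_col),
                 variableLengthString = TRUE)
  h5_write_attr(file, paste0(group, "/", index_col),
                "encoding-type", "string-array")
  h5_write_attr(file, paste0(group, "/", index_col),
                "encoding-version", "0.2.0")
  cols <- setdiff(names(df), index_col)
  for (cn in cols) {
    v <- df[[cn]]
    path <- paste0(group, "/", cn)
    if (is.numeric(v)) {
      rhdf5::h5write(as.double(v), file, path)
      h5_write_attr(file, path, "encoding-type", "array")
    } else {
      rhdf5::h5write(as.character(v), file, path, variableLengthString = TRUE)
      h5_write_attr(file, path, "encoding-type", "string-array")
    }
    h5_write_attr(file, path, "encoding-version", "0.2.0")
  }
  h5_write_attr(file, group, "encoding-type", "dataframe")
  h5_write_attr(file, group, "encoding-version", "0.2.0")
  h5_write_attr(file, group, "_index", index_col)
  if (length(cols)) {
    h5_write_attr(file, group, "column-order", cols)
  } else {
    h5_write_empty_string_attr(file, group, "column-order")
  }
}

#' Write a mutation matrix to an AnnData-convention HDF5 file
#'
#' The on-disk layout follows the `.h5ad` convention: the count matrix under
#' `/X` as a compressed-sparse-row group, per-cell annotations under `/obs`,
#' per-gene annotations under `/var`, and any 2-D embeddings under `/obsm`.
#' Files written here are readable by the Python `anndata` package and by
#' [read_matrix()].
#'
#' @param m A `mutation_matrix`.
#' @param path Output file path (conventionally `.h5ad`).
#' @param obsm Optional named list of numeric matrices (n_cells x k), stored
#'   under `/obsm` (e.g. `X_umap`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, obsm = NULL) {
  stopifnot(inherits(m, "mutation_matrix"))
  if (nrow(m$counts) == 0 || ncol(m$counts) == 0) stop("empty matrix")
  if (file.exists(path) && unlink(path) != 0) {
    stop("cannot overwrite ", path)
  }
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) stop("cannot write to ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  # CSR on disk = CSC of the transposed matrix
  xt <- methods::as(Matrix::t(m$counts), "CsparseMatrix")
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(as.double(xt@x), path, "X/data")
  rhdf5::h5write(as.integer(xt@i), path, "X/indices")
  rhdf5::h5write(as.integer(xt@p), path, "X/indptr")
  h5_write_attr(path, "X", "encoding-type", "csr_matrix")
  h5_write_attr(path, "X", "encoding-version", "0.1.0")
  h5_write_attr(path, "X", "shape", as.integer(dim(m$counts)))

  obs <- m$obs
  names(obs)[names(obs) == "cell_id"] <- "_index"
  h5_write_dataframe(path, "obs", obs, "_index")
  var <- m$var
  names(var)[names(var) == "gene_id"] <- "_index"
  h5_write_dataframe(path, "var", var, "_index")

  if (!is.null(obsm) && length(obsm)) {
    rhdf5::h5createGroup(path, "obsm")
    for (nm in names(obsm)) {
      stopifnot(nrow(obsm[[nm]]) == nrow(m$counts))
      # anndata stores obsm row-major; h5write writes column-major, so store t()
      rhdf5::h5write(t(as.matrix(obsm[[nm]])), path, paste0("obsm/", nm))
      h5_write_attr(path, paste0("obsm/", nm), "encoding-type", "array")
      h5_write_attr(path, paste0("obsm/", nm), "encoding-version", "0.2.0")
    }
    h5_write_attr(path, "obsm", "encoding-type", "dict")
    h5_write_attr(path, "obsm", "encoding-version", "0.1.0")
  }
  h5_write_attr(path, "/", "encoding-type", "anndata")
  h5_write_attr(path, "/", "encoding-version", "0.1.0")
  invisible(path)
}

h5_read_dataframe <- function(path, group) {
  info <- rhdf5::h5ls(path)
  dsets <- info$name[info$group == paste0("/", group) & info$otype == "H5I_DATASET"]
  idx_col <- tryCatch(
    rhdf5::h5readAttributes(path, group)[["_index"]],
    error = function(e) NULL
  )
  if (is.null(idx_col)) idx_col <- "_index"
  vals <- lapply(dsets, function(d) {
    v <- rhdf5::h5read(path, paste0(group, "/", d))
    if (is.array(v)) v <- as.vector(v)
    v
  })
  names(vals) <- dsets
  order_attr <- tryCatch(
    rhdf5::h5readAttributes(path, group)[["column-order"]],
    error = function(e) NULL
  )
  cols <- c(idx_col, intersect(as.character(order_attr), dsets),
            setdiff(dsets, c(idx_col, as.character(order_attr))))
  cols <- unique(cols)
  df <- tibble::as_tibble(vals[cols])
  names(df)[names(df) == idx_col] <- "_index"
  df
}

#' Read a mutation matrix from an AnnData-convention HDF5 file
#'
#' Inverse of [write_matrix()]: `read_matrix(write_matrix(m, p))` reproduces
#' `m` exactly (counts, labels and annotations). Dense or CSR/CSC sparse `/X`
#' layouts are accepted.
#'
#' @param path Path to the `.h5ad`-convention file.
#' @return A `mutation_matrix`. If the file carries `/obsm` entries they are
#'   attached as an `obsm` attribute (named list of matrices).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  info <- rhdf5::h5ls(path)
  xattr <- rhdf5::h5readAttributes(path, "X")
  obs <- h5_read_dataframe(path, "obs")
  var <- h5_read_dataframe(path, "var")
  n_cells <- nrow(obs)
  n_genes <- nrow(var)
  if ("X" %in% info$name[info$group == "/"] &&
      info$otype[info$group == "/" & info$name == "X"] == "H5I_DATASET") {
    x <- rhdf5::h5read(path, "X")
    counts <- Matrix::Matrix(t(x), sparse = TRUE) # stored row-major
  } else {
    enc <- xattr[["encoding-type"]]
    data <- as.double(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shape <- as.integer(xattr[["shape"]])
    if (identical(enc, "csc_matrix")) {
      counts <- Matrix::sparseMatrix(
        i = indices + 1L, p = indptr, x = data,
        dims = shape, index1 = TRUE
      )
    } else {
      counts <- Matrix::t(Matrix::sparseMatrix(
        i = indices + 1L, p = indptr, x = data,
        dims = rev(shape), index1 = TRUE
      ))
    }
  }
  rownames(counts) <- obs[["_index"]]
  colnames(counts) <- var[["_index"]]
  names(obs)[names(obs) == "_index"] <- "cell_id"
  names(var)[names(var) == "_index"] <- "gene_id"
  m <- mutation_matrix(counts, obs = obs, var = var)
  if (any(info$group == "/obsm")) {
    nms <- info$name[info$group == "/obsm"]
    obsm <- lapply(nms, function(nm) t(rhdf5::h5read(path, paste0("obsm/", nm))))
    names(obsm) <- nms
    attr(m, "obsm") <- obsm
  }
  stopifnot(nrow(m$counts) == n_cells, ncol(m$counts) == n_genes)
  m
}

#' Export the count matrix as a plain TSV
#'
#' A language-neutral export: cells in rows, genes in columns, first column
#' `cell_id`.
#'
#' @param m A `mutation_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_matrix_tsv <- function(m, path) {
  df <- as.data.frame(as.matrix(m$counts), check.names = FALSE)
  df <- cbind(cell_id = rownames(df), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
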