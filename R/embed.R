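#' Principal components and a fuzzy kNN cell graph
#'
#' Computes PCA scores of the processed matrix (exact SVD for small inputs,
#' truncated via irlba otherwise; component signs fixed so the largest
#' absolute loading is positive, making scores reproducible and independent
#' of cell order), finds the `n_neighbors` nearest neighbors of every cell in
#' PC space, and converts distances into a symmetric fuzzy-simplicial
#' connectivity graph (UMAP-style local scaling: per-cell distance offset at
#' the nearest neighbor, bandwidth calibrated so effective neighborhood size
#' is log2(k), then probabilistic union of the directed graphs).
#'
#' @param values Dense processed matrix, cells x genes.
#' @param n_pcs Number of components (capped at `min(dim(values)) - 1`).
#' @param n_neighbors Neighborhood size; must be `< n_cells`.
#' @param seed Seed for the truncated-SVD initialization.
#' @return A list: `scores` (cells x n_pcs), `graph` (sparse symmetric
#'   dgCMatrix of connectivities, zero diagonal), `knn` (list `idx`, `dist`
#'   excluding self).
#' @export
reduce_and_graph <- function(values, n_pcs = 50L, n_neighbors = 15L,
                             seed = 0L) {
  values <- as.matrix(values)
  n_cells <- nrow(values)
  if (n_cells <= n_neighbors) {
    stop("n_cells (", n_cells, ") must exceed n_neighbors (", n_neighbors,
         "); use a smaller n_neighbors")
  }
  stopifnot(n_pcs >= 2, n_neighbors >= 2)
  n_pcs <- min(n_pcs, min(dim(values)) - 1L)
  centered <- sweep(values, 2, colMeans(values))
  if (n_pcs >= min(dim(values)) / 2 || min(dim(values)) < 100) {
    sv <- svd(centered, nu = n_pcs, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  } else {
    set.seed(seed)
    sv <- irlba::irlba(centered, nv = n_pcs)
    scores <- sv$u %*% diag(sv$d, n_pcs)
  }
  # deterministic sign: largest-|u| entry of each component positive
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(values)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))

  nn <- RANN::nn2(scores, k = n_neighbors + 1L)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  dist <- nn$nn.dists[, -1, drop = FALSE]
  rownames(idx) <- rownames(values)
  graph <- fuzzy_connectivities(idx, dist)
  dimnames(graph) <- list(rownames(values), rownames(values))
  list(scores = scores, graph = graph,
       knn = list(idx = idx, dist = dist))
}

# UMAP-style fuzzy simplicial set from a kNN index/distance pair.
fuzzy_connectivities <- function(idx, dist, bandwidth_iters = 64L) {
  n <- nrow(idx)
  k <- ncol(idx)
  target <- log2(k + 1)
  rho <- apply(dist, 1, function(d) {
    dd <- d[d > 0]
    if (length(dd)) min(dd) else 0
  })
  sigma <- vapply(seq_len(n), function(i) {
    d <- pmax(dist[i, ] - rho[i], 0)
    if (all(d == 0)) return(1)
    lo <- 0
    hi <- max(d) * k
    for (iter in seq_len(bandwidth_iters)) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  w <- exp(-pmax(dist - rho, 0) / sigma)
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k),
    j = as.vector(idx),
    x = as.vector(w),
    dims = c(n, n)
  )
  at <- Matrix::t(a)
  had <- a * at
  g <- a + at - had # probabilistic t-conorm union
  Matrix::diag(g) <- 0
  Matrix::drop0(methods::as(g, "CsparseMatrix"))
}

#' 2-D UMAP embedding from the cell graph
#'
#' Runs the UMAP layout on the precomputed kNN structure (single-threaded,
#' fixed seed), so the embedding and the clustering share one neighbor graph
#' and repeated runs are bit-identical.
#'
#' @param knn List `idx`, `dist` from [reduce_and_graph()].
#' @param seed Layout seed.
#' @param n_components Embedding dimension (2).
#' @return n_cells x 2 matrix of finite coordinates.
#' @export
umap_embed <- function(knn, seed = 0L, n_components = 2L) {
  if (is.null(knn$idx) || nrow(knn$idx) < 3) {
    stop("degenerate graph: need at least 3 cells with neighbors")
  }
  # uwot expects self in the neighbor list
  idx <- cbind(seq_len(nrow(knn$idx)), knn$idx)
  dist <- cbind(0, knn$dist)
  set.seed(seed)
  coords <- uwot::umap(
    X = NULL,
    nn_method = list(idx = idx, dist = dist),
    n_components = n_components,
    # spectral initialization needs enough cells for the truncated
    # eigendecomposition; fall back to seeded random placement below that
    init = if (nrow(idx) >= 10) "spectral" else "random",
    n_threads = 1, n_sgd_threads = 0,
    batch = FALSE, verbose = FALSE
  )
  if (!all(is.finite(coords))) stop("non-finite embedding coordinates")
  rn <- rownames(knn$idx)
  dimnames(coords) <- list(rn, paste0("UMAP", seq_len(n_components)))
  coords
}

#' Graph community detection with Leiden or Louvain
#'
#' Builds the weighted undirected cell graph from the connectivity matrix and
#' partitions it. Cluster labels are `0 .. K-1`, renumbered by descending
#' cluster size so naming is stable; results are deterministic for a fixed
#' seed.
#'
#' @param graph Sparse symmetric connectivity matrix.
#' @param algorithm `"leiden"` or `"louvain"`.
#' @param resolution Resolution parameter (default 1).
#' @param seed RNG seed.
#' @return Factor of cluster labels, one per cell, levels `0 .. K-1`.
#' @export
cluster_cells <- function(graph, algorithm = c("leiden", "louvain"),
                          resolution = 1, seed = 0L) {
  if (!is.character(algorithm) ||
      !all(algorithm %in% c("leiden", "louvain"))) {
    stop("unknown algorithm: valid options are \"leiden\", \"louvain\"")
  }
  algorithm <- match.arg(algorithm)
  g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  set.seed(seed)
  comm <- if (algorithm == "leiden") {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5)
  } else {
    igraph::cluster_louvain(g, resolution = resolution)
  }
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  lab <- remap[as.character(raw)]
  factor(lab, levels = sort(unique(lab)))
}

#' Embed and cluster a preprocessed dataset
#'
#' PCA, kNN graph, UMAP layout and both Leiden and Louvain labelings in one
#' call; the standard continuation of [qc_preprocess()].
#'
#' @param qc A `qc_result`.
#' @param config Defaults to the config stored in `qc`.
#' @return A list of class `embedding_result`: `coords` (n_cells x 2),
#'   `leiden`, `louvain` (factors aligned to cell order), `graph`, `scores`,
#'   `config`.
#' @export
embed_cluster <- function(qc, config = qc$config) {
  red <- reduce_and_graph(qc$values, n_pcs = config$n_pcs,
                          n_neighbors = config$n_neighbors,
                          seed = config$seed)
  coords <- umap_embed(red$knn, seed = config$seed)
  leiden <- cluster_cells(red$graph, "leiden",
                          resolution = config$resolution, seed = config$seed)
  louvain <- cluster_cells(red$graph, "louvain",
                           resolution = config$resolution, seed = config$seed)
  structure(list(
    coords = coords, leiden = leiden, louvain = louvain,
    graph = red$graph, scores = red$scores, config = config
  ), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "<embedding_result> %d cells; %d Leiden / %d Louvain clusters\n",
    nrow(x$coords), nlevels(x$leiden), nlevels(x$louvain)
  ))
  invisible(x)
}

#' Tidy method for embedding results
#'
#' @param x An `embedding_result`.
#' @param ... Unused.
#' @return Tibble: `cell_id`, `UMAP1`, `UMAP2`, `leiden`, `louvain`.
#' @method tidy embedding_result
#' @export
tidy.embedding_result <- function(x, ...) {
  tibble::tibble(
    cell_id = rownames(x$coords),
    UMAP1 = x$coords[, 1],
    UMAP2 = x$coords[, 2],
    leiden = x$leiden,
    louvain = x$louvain
  )
}

#' @method glance embedding_result
#' @export
glance.embedding_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$coords),
    n_leiden = nlevels(x$leiden),
    n_louvain = nlevels(x$louvain),
    ari_leiden_louvain = adjusted_rand_index(x$leiden, x$louvain)
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Vectors or factors of equal length.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
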