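#' @import ggplot2
NULL

#' QC plot: distribution of mutated cells per gene
#'
#' Histogram of the number of cells each gene is mutated in, with a vertical
#' line at the minimum-cells-per-gene cutoff.
#'
#' @param m Pre-filter `mutation_matrix`.
#' @param cutoff The configured minimum cells per gene.
#' @return A ggplot object.
#' @export
plot_cells_per_gene <- function(m, cutoff = 3) {
  df <- tibble::tibble(cells_per_gene = Matrix::colSums(m$counts > 0))
  ggplot(df, aes(x = .data$cells_per_gene)) +
    geom_histogram(bins = 50, fill = "grey35") +
    geom_vline(xintercept = cutoff, colour = "red", linetype = "dashed") +
    scale_x_log10() +
    labs(x = "Cells per gene (mutated)", y = "Genes",
         title = sprintf("Genes mutated in < %g cells are removed", cutoff)) +
    theme_bw()
}

#' QC plot: distribution of mutated genes per cell
#'
#' Histogram of per-cell mutated-gene counts with the lower (minimum genes)
#' and upper (percentile) cutoff lines.
#'
#' @param m `mutation_matrix` at the stage the cutoffs apply to.
#' @param lower Minimum mutated genes per cell.
#' @param upper Upper percentile threshold (in gene-count units).
#' @return A ggplot object.
#' @export
plot_genes_per_cell <- function(m, lower = 30, upper = NULL) {
  df <- tibble::tibble(genes_per_cell = Matrix::rowSums(m$counts > 0))
  p <- ggplot(df, aes(x = .data$genes_per_cell)) +
    geom_histogram(bins = 50, fill = "grey35") +
    geom_vline(xintercept = lower, colour = "red", linetype = "dashed") +
    labs(x = "Mutated genes per cell", y = "Cells",
         title = "Per-cell mutated-gene counts with lower/upper cutoffs") +
    theme_bw()
  if (!is.null(upper)) {
    p <- p + geom_vline(xintercept = upper, colour = "blue",
                        linetype = "dashed")
  }
  p
}

#' QC plot: mean-dispersion scatter with selected HVGs highlighted
#'
#' @param hvg_table The per-gene table from [select_hvg()] (or `qc$hvg`).
#' @return A ggplot object.
#' @export
plot_hvg_dispersion <- function(hvg_table) {
  ggplot(hvg_table, aes(x = .data$mean, y = .data$dispersion_norm,
                        colour = .data$selected)) +
    geom_point(size = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "black"),
                        name = "highly variable") +
    labs(x = "Mean expm1 value", y = "Normalized dispersion",
         title = "Highly variable gene selection") +
    theme_bw()
}

#' Write the three QC plots for a preprocessing run
#'
#' Deterministic file names under `out_dir`: `qc_cells_per_gene.png`,
#' `qc_genes_per_cell.png`, `qc_hvg_dispersion.png`.
#'
#' @param qc A `qc_result`.
#' @param raw The pre-filter `mutation_matrix`.
#' @param out_dir Output directory (created if needed).
#' @param dpi Raster resolution (default 150).
#' @return Character vector of file paths, invisibly.
#' @export
qc_plots <- function(qc, raw, out_dir, dpi = 150) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rep <- qc$report
  upper_row <- rep[rep$step == "filter_cells_upper_percentile", ]
  m_before_cells <- filter_genes_min_cells(raw, qc$config$min_cells_per_gene)
  paths <- c(
    file.path(out_dir, "qc_cells_per_gene.png"),
    file.path(out_dir, "qc_genes_per_cell.png"),
    file.path(out_dir, "qc_hvg_dispersion.png")
  )
  save_plot(plot_cells_per_gene(raw, qc$config$min_cells_per_gene),
            paths[1], dpi)
  save_plot(plot_genes_per_cell(m_before_cells, qc$config$min_genes_per_cell,
                                upper = upper_row$threshold[1]),
            paths[2], dpi)
  save_plot(plot_hvg_dispersion(qc$hvg), paths[3], dpi)
  invisible(paths)
}

save_plot <- function(p, path, dpi = 150, width = 6, height = 4.5) {
  ggsave(path, plot = p, dpi = dpi, width = width, height = height,
         device = grDevices::png)
  invisible(path)
}

#' UMAP scatter plots colored by metadata and cluster labels
#'
#' One plot per requested coloring. By default every auto-detected
#' categorical metadata column plus both cluster labelings is used. Numeric
#' columns are rejected: coloring is categorical by design, matching the
#' automatic selection of non-numeric metadata columns.
#'
#' @param emb An `embedding_result`.
#' @param obs Per-cell annotation tibble aligned to the embedding (e.g.
#'   `qc$matrix$obs`).
#' @param color_by Character vector of obs columns and/or `"leiden"`,
#'   `"louvain"`; `NULL` for the default set.
#' @return Named list of ggplot objects.
#' @export
plot_umap <- function(emb, obs, color_by = NULL) {
  df <- tidy(emb)
  df <- dplyr::left_join(df, obs, by = "cell_id")
  if (is.null(color_by)) {
    color_by <- c(categorical_columns(obs), "leiden", "louvain")
    color_by <- setdiff(color_by, c("cell_id"))
  }
  plots <- lapply(color_by, function(cn) {
    if (!cn %in% names(df)) {
      stop("unknown column \"", cn, "\" for coloring; available: ",
           paste(c(categorical_columns(obs), "leiden", "louvain"),
                 collapse = ", "))
    }
    if (is.numeric(df[[cn]])) {
      stop("column \"", cn, "\" is numeric; UMAP coloring uses categorical ",
           "columns only (", paste(categorical_columns(obs), collapse = ", "),
           ")")
    }
    vals <- as.character(df[[cn]])
    vals[is.na(vals)] <- "NA"
    df$.colour <- vals
    ggplot(df, aes(x = .data$UMAP1, y = .data$UMAP2,
                   colour = .data$.colour)) +
      geom_point(size = 1.6) +
      labs(colour = cn, title = paste("UMAP colored by", cn)) +
      theme_bw()
  })
  names(plots) <- color_by
  plots
}

#' @method autoplot embedding_result
#' @export
autoplot.embedding_result <- function(object, color_by = "leiden", obs = NULL,
                                      ...) {
  if (is.null(obs)) obs <- tibble::tibble(cell_id = rownames(object$coords))
  plot_umap(object, obs, color_by = color_by)[[1]]
}

# ---- Venn rendering ----------------------------------------------------------

venn_shapes <- function(k) {
  if (k == 2) {
    tibble::tibble(
      set = 1:2, cx = c(-0.45, 0.45), cy = c(0, 0),
      a = c(1, 1), b = c(1, 1), angle = c(0, 0)
    )
  } else if (k == 3) {
    tibble::tibble(
      set = 1:3,
      cx = c(0, -0.55, 0.55), cy = c(0.62, -0.35, -0.35),
      a = rep(1, 3), b = rep(1, 3), angle = rep(0, 3)
    )
  } else {
    # classic 4-ellipse layout on the unit square
    tibble::tibble(
      set = 1:4,
      cx = c(0.350, 0.450, 0.544, 0.644),
      cy = c(0.400, 0.500, 0.500, 0.400),
      a = rep(0.72 / 2, 4), b = rep(0.45 / 2, 4),
      angle = c(140, 140, 40, 40) * pi / 180
    )
  }
}

in_ellipse <- function(x, y, cx, cy, a, b, angle) {
  dx <- x - cx
  dy <- y - cy
  xr <- cos(-angle) * dx - sin(-angle) * dy
  yr <- sin(-angle) * dx + cos(-angle) * dy
  (xr / a)^2 + (yr / b)^2 <= 1
}

ellipse_outline <- function(row, n = 200) {
  t <- seq(0, 2 * pi, length.out = n)
  x0 <- row$a * cos(t)
  y0 <- row$b * sin(t)
  tibble::tibble(
    set = row$set,
    x = row$cx + cos(row$angle) * x0 - sin(row$angle) * y0,
    y = row$cy + sin(row$angle) * x0 + cos(row$angle) * y0
  )
}

# label position = centroid of grid points lying in exactly that region
venn_label_positions <- function(shapes, grid_n = 251) {
  k <- nrow(shapes)
  xr <- range(shapes$cx) + c(-1, 1) * max(shapes$a) * 1.1
  yr <- range(shapes$cy) + c(-1, 1) * max(shapes$a) * 1.1
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  pts <- expand.grid(x = gx, y = gy)
  memb <- vapply(seq_len(k), function(i) {
    s <- shapes[i, ]
    in_ellipse(pts$x, pts$y, s$cx, s$cy, s$a, s$b, s$angle)
  }, logical(nrow(pts)))
  code <- memb %*% (2^(seq_len(k) - 1))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    pat <- as.logical(combos[i, ])
    cc <- sum(2^(which(pat) - 1))
    sel <- code == cc
    tibble::tibble(
      pattern = paste(as.integer(pat), collapse = ""),
      x = if (any(sel)) mean(pts$x[sel]) else NA_real_,
      y = if (any(sel)) mean(pts$y[sel]) else NA_real_
    )
  })
}

#' Render a 2-4-set Venn diagram of mutated-gene sets
#'
#' Draws circles (2-3 sets) or rotated ellipses (4 sets) and labels every
#' exclusive region with its count from [venn_counts()].
#'
#' @param x A `gene_set_collection` or named list of 2-4 sets.
#' @param counts Optional precomputed [venn_counts()] output (recomputed if
#'   `NULL`).
#' @return A ggplot object. Region labels equal the `count` column of
#'   [venn_counts()].
#' @export
plot_venn <- function(x, counts = NULL) {
  sets <- if (inherits(x, "gene_set_collection")) x$sets else x
  k <- length(sets)
  if (k < 2 || k > 4) stop("Venn rendering supports 2-4 sets")
  if (is.null(counts)) counts <- venn_counts(sets)
  shapes <- venn_shapes(k)
  outlines <- purrr::map_dfr(seq_len(k), function(i) {
    ellipse_outline(shapes[i, ])
  })
  labels <- venn_label_positions(shapes)
  nms <- names(sets)
  counts$pattern <- purrr::map_chr(counts$sets, function(s) {
    paste(as.integer(nms %in% s), collapse = "")
  })
  labels <- dplyr::left_join(labels, counts[, c("pattern", "count")],
                             by = "pattern")
  set_labels <- purrr::map_dfr(seq_len(k), function(i) {
    s <- shapes[i, ]
    tibble::tibble(
      name = nms[i],
      x = s$cx + cos(s$angle + pi / 2) * s$b * 1.25,
      y = s$cy + sin(s$angle + pi / 2) * s$b * 1.25
    )
  })
  ggplot() +
    geom_path(data = outlines,
              aes(x = .data$x, y = .data$y, group = .data$set,
                  colour = factor(.data$set)), linewidth = 0.8) +
    geom_text(data = labels[!is.na(labels$x), ],
              aes(x = .data$x, y = .data$y, label = .data$count), size = 4) +
    geom_text(data = set_labels,
              aes(x = .data$x, y = .data$y, label = .data$name),
              fontface = "bold", size = 4) +
    coord_equal() +
    guides(colour = "none") +
    theme_void()
}

#' Render and save the Venn diagram
#'
#' @param x A `gene_set_collection`.
#' @param path Output PNG path.
#' @param dpi Raster resolution.
#' @return `path`, invisibly; the rendered counts as attribute `counts`.
#' @export
render_venn <- function(x, path, dpi = 150) {
  counts <- venn_counts(x)
  p <- plot_venn(x, counts)
  save_plot(p, path, dpi = dpi, width = 6, height = 6)
  invisible(structure(path, counts = counts))
}
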