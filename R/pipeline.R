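#' Convert annotation files and metadata into an AnnData-convention file
#'
#' The `convert` stage: ingest per-cell ANNOVAR tables (directory or ZIP)
#' plus the metadata table, assemble the cells-by-genes mutation-count
#' matrix, and serialize it (HDF5 AnnData convention plus a TSV export and a
#' JSON run manifest).
#'
#' @param input Directory or ZIP of per-cell annotation files.
#' @param metadata Path to the metadata CSV/TSV (or `NULL`).
#' @param out Output `.h5ad` path.
#' @param config A [pipeline_config()].
#' @param strict Error on cells without metadata match.
#' @param quiet Suppress progress messages.
#' @return The `mutation_matrix`, invisibly; files written next to `out`.
#' @export
run_convert <- function(input, metadata, out, config = pipeline_config(),
                        strict = FALSE, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else message
  m <- ingest_variants(input, metadata, config = config, strict = strict)
  say(sprintf("convert: %d cells x %d genes (%d mutation records)",
              nrow(m$counts), ncol(m$counts), sum(m$counts)))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_matrix(m, out)
  export_matrix_tsv(m, paste0(tools::file_path_sans_ext(out), "_counts.tsv"))
  write_manifest(
    command = "convert", config = config,
    inputs = c(input, if (!is.null(metadata)) metadata),
    outputs = out,
    path = paste0(tools::file_path_sans_ext(out), "_manifest.json")
  )
  invisible(m)
}

#' Run QC, embedding, clustering and reports on a converted matrix
#'
#' The `umap` stage: load the matrix, run the five-step preprocessing chain,
#' embed with UMAP, cluster with Leiden and Louvain, and write UMAP plots, QC
#' plots, the Venn diagram, the per-patient summary report, the filter
#' report, a coordinates/labels TSV and an updated matrix file carrying the
#' embedding and cluster labels.
#'
#' @param matrix_file Path to the `.h5ad`-convention file from
#'   [run_convert()], or a `mutation_matrix` object.
#' @param out_dir Output directory for all artifacts.
#' @param config A [pipeline_config()].
#' @param color_by Columns for UMAP coloring (`NULL`: all categorical columns
#'   plus both cluster labelings).
#' @param group_by Categorical column for the Venn grouping (`NULL`: the
#'   first non-id categorical column, falling back to `sample_id`).
#' @param patient_column Patient id column (default `"sample_id"`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `qc`, `embedding`, `summary`, `venn` (counts
#'   tibble or `NULL`), `files`.
#' @export
run_umap <- function(matrix_file, out_dir, config = pipeline_config(),
                     color_by = NULL, group_by = NULL,
                     patient_column = "sample_id", quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else message
  raw <- if (inherits(matrix_file, "mutation_matrix")) {
    matrix_file
  } else {
    read_matrix(matrix_file)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  qc <- qc_preprocess(raw, config)
  for (i in seq_len(nrow(qc$report))) {
    say(sprintf(
      "qc step %s: cells %d -> %d, genes %d -> %d",
      qc$report$step[i],
      qc$report$n_cells_before[i], qc$report$n_cells_after[i],
      qc$report$n_genes_before[i], qc$report$n_genes_after[i]
    ))
  }
  emb <- embed_cluster(qc, config)
  say(sprintf("clustering: %d Leiden / %d Louvain clusters",
              nlevels(emb$leiden), nlevels(emb$louvain)))

  files <- character(0)
  files <- c(files, qc_plots(qc, raw, out_dir))

  umaps <- plot_umap(emb, qc$matrix$obs, color_by = color_by)
  for (nm in names(umaps)) {
    f <- file.path(out_dir, paste0("umap_", nm, ".png"))
    save_plot(umaps[[nm]], f)
    files <- c(files, f)
  }

  coords_tbl <- tidy(emb)
  coords_path <- file.path(out_dir, "umap_coords.tsv")
  readr::write_tsv(coords_tbl, coords_path)
  files <- c(files, coords_path)

  files <- c(files, write_filter_report(
    qc$report, file.path(out_dir, "filter_report")
  ))

  summary_tbl <- NULL
  venn_tbl <- NULL
  if (patient_column %in% names(raw$obs)) {
    summary_tbl <- summary_report(qc, raw, patient_column)
    files <- c(files, write_summary_report(
      summary_tbl, file.path(out_dir, "summary_report")
    ))
    gb <- group_by
    if (is.null(gb)) {
      cand <- setdiff(categorical_columns(qc$matrix$obs),
                      c("cell_id", patient_column))
      gb <- if (length(cand)) cand[1] else patient_column
    }
    qsets <- suppressWarnings(qualifying_genes(qc$matrix, patient_column))
    n_groups <- length(unique(as.character(qc$matrix$obs[[gb]])))
    if (n_groups >= 2 && n_groups <= 4) {
      coll <- group_sets(qsets, qc$matrix$obs, gb,
                         patient_column = patient_column)
      venn_tbl <- venn_counts(coll)
      venn_path <- file.path(out_dir, "venn.png")
      render_venn(coll, venn_path)
      files <- c(files, venn_path, write_venn_regions(
        venn_tbl, file.path(out_dir, "venn_regions.tsv")
      ))
    } else {
      say(sprintf("venn: skipped (%d groups in \"%s\"; need 2-4)",
                  n_groups, gb))
    }
  }

  mat_path <- file.path(out_dir, "matrix_processed.h5ad")
  m_out <- qc$matrix
  m_out$obs$leiden <- as.character(emb$leiden)
  m_out$obs$louvain <- as.character(emb$louvain)
  write_matrix(m_out, mat_path, obsm = list(X_umap = emb$coords))
  files <- c(files, mat_path)

  write_manifest(
    command = "umap", config = config,
    inputs = if (is.character(matrix_file)) matrix_file else character(0),
    outputs = files,
    path = file.path(out_dir, "run_manifest.json")
  )
  invisible(list(qc = qc, embedding = emb, summary = summary_tbl,
                 venn = venn_tbl, files = files))
}

#' Run the full pipeline: convert then umap
#'
#' Composition of [run_convert()] and [run_umap()]; the intermediate matrix
#' file is kept under `out_dir`.
#'
#' @inheritParams run_convert
#' @inheritParams run_umap
#' @param out_dir Output directory for every artifact.
#' @return Invisibly, the [run_umap()] result with the matrix path added.
#' @export
run_all <- function(input, metadata, out_dir, config = pipeline_config(),
                    color_by = NULL, group_by = NULL,
                    patient_column = "sample_id", strict = FALSE,
                    quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(out_dir, "matrix.h5ad")
  run_convert(input, metadata, mat_path, config = config, strict = strict,
              quiet = quiet)
  res <- run_umap(mat_path, out_dir, config = config, color_by = color_by,
                  group_by = group_by, patient_column = patient_column,
                  quiet = quiet)
  res$matrix_file <- mat_path
  invisible(res)
}

write_manifest <- function(command, config, inputs, outputs, path) {
  hash_of <- function(f) {
    if (file.exists(f) && !dir.exists(f)) unname(tools::md5sum(f)) else NA
  }
  manifest <- list(
    command = command,
    tool = "mutumap",
    version = as.character(utils::packageVersion("mutumap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = lapply(inputs, function(f) list(path = f, md5 = hash_of(f))),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
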