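#' Per-patient qualifying mutated-gene sets
#'
#' A gene qualifies for a patient when it is mutated (nonzero count) in at
#' least `min_cells` of that patient's cells — the rule behind the published
#' per-patient "mutated genes" counts and the Venn analysis. Applied to the
#' post-filter count matrix by default.
#'
#' @param m A `mutation_matrix`.
#' @param patient_column Name of the categorical obs column holding the
#'   patient/sample id (default `"sample_id"`).
#' @param min_cells Minimum supporting cells per patient (default 2).
#' @return Named list: patient -> character vector of qualifying genes.
#'   Patients with fewer than `min_cells` cells get an empty set with a
#'   warning.
#' @export
qualifying_genes <- function(m, patient_column = "sample_id",
                             min_cells = 2L) {
  stopifnot(inherits(m, "mutation_matrix"), min_cells >= 1)
  check_categorical_column(m, patient_column)
  patients <- m$obs[[patient_column]]
  out <- lapply(split(seq_len(nrow(m$counts)), patients), function(rows) {
    if (length(rows) < min_cells) return(character(0))
    support <- Matrix::colSums(m$counts[rows, , drop = FALSE] > 0)
    names(support)[support >= min_cells]
  })
  small <- names(out)[table(patients)[names(out)] < min_cells]
  if (length(small)) {
    warning("patient(s) with fewer than ", min_cells, " cells get empty sets: ",
            paste(small, collapse = ", "))
  }
  out
}

check_categorical_column <- function(m, column) {
  if (!column %in% names(m$obs)) {
    stop("unknown column \"", column, "\"; available categorical columns: ",
         paste(categorical_columns(m$obs), collapse = ", "))
  }
  if (is.numeric(m$obs[[column]])) {
    stop("column \"", column, "\" is numeric; grouping and coloring require ",
         "a categorical column (",
         paste(categorical_columns(m$obs), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Group-level mutated-gene sets for Venn analysis
#'
#' Each group's set is the union of its member patients' qualifying sets.
#' At most 4 groups are supported (the Venn renderer's limit).
#'
#' @param per_patient_sets Output of [qualifying_genes()].
#' @param obs Per-cell annotation tibble holding both columns.
#' @param group_column Categorical obs column defining the groups.
#' @param patient_column Column linking cells to patients.
#' @return A list of class `gene_set_collection`: `group_column`, `sets`
#'   (named list group -> gene set), `per_patient_sets`.
#' @export
group_sets <- function(per_patient_sets, obs, group_column,
                       patient_column = "sample_id") {
  stopifnot(group_column %in% names(obs), patient_column %in% names(obs))
  if (is.numeric(obs[[group_column]])) {
    stop("column \"", group_column, "\" is numeric; choose a categorical column")
  }
  map <- dplyr::distinct(obs[, c(patient_column, group_column)])
  groups <- sort(unique(as.character(map[[group_column]])))
  if (length(groups) > 4) {
    stop(length(groups), " groups in \"", group_column,
         "\": the Venn renderer supports at most 4; subset the data or ",
         "choose another column")
  }
  sets <- lapply(groups, function(g) {
    pats <- as.character(map[[patient_column]][map[[group_column]] == g])
    sort(unique(unlist(per_patient_sets[pats], use.names = FALSE)))
  })
  names(sets) <- groups
  structure(list(group_column = group_column, sets = sets,
                 per_patient_sets = per_patient_sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> grouped by", x$group_column, "\n")
  for (g in names(x$sets)) cat(sprintf("  %s: %d genes\n", g, length(x$sets[[g]])))
  invisible(x)
}

#' Exclusive Venn-region counts for 2-4 sets
#'
#' Partitions the union of the sets into the 2^k - 1 exclusive Venn regions
#' and counts each region's elements; the counts sum to the size of the
#' union.
#'
#' @param x A `gene_set_collection`, or a named list of 2-4 character sets.
#' @return Tibble: `region` (e.g. `"A&B"` using set names), `sets` (list of
#'   member set names), `count`, `genes` (list of region members).
#' @export
venn_counts <- function(x) {
  sets <- if (inherits(x, "gene_set_collection")) x$sets else x
  k <- length(sets)
  if (k < 2) stop("venn_counts needs at least 2 sets")
  if (k > 4) stop("venn_counts supports at most 4 sets")
  nms <- names(sets)
  stopifnot(!is.null(nms), !anyDuplicated(nms))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- nms
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    pat <- as.logical(combos[i, ])
    in_region <- if (length(universe)) {
      apply(member, 1, function(row) all(row == pat))
    } else logical(0)
    tibble::tibble(
      region = paste(nms[pat], collapse = "&"),
      sets = list(nms[pat]),
      count = sum(in_region),
      genes = list(universe[in_region])
    )
  })
}

#' Per-patient summary report
#'
#' One row per patient seen in the raw input: cells before filtering, cells
#' surviving, the mean per-cell retained variant count on the post-filter
#' matrix, and the number of qualifying mutated genes. Patients whose cells
#' were all removed are flagged `"no cells passed filtering"` with blank
#' statistics.
#'
#' @param qc A `qc_result` from [qc_preprocess()].
#' @param raw The pre-filter `mutation_matrix` given to [qc_preprocess()].
#' @param patient_column Patient id column (default `"sample_id"`).
#' @param min_cells Qualifying-gene support threshold (default 2).
#' @return A tibble of class `summary_report`: `patient`, `n_cells`,
#'   `n_filtered_cells`, `mean_mutations_per_cell`, `n_mutated_genes`,
#'   `note`.
#' @export
summary_report <- function(qc, raw, patient_column = "sample_id",
                           min_cells = 2L) {
  stopifnot(inherits(qc, "qc_result"), inherits(raw, "mutation_matrix"))
  check_categorical_column(raw, patient_column)
  m <- qc$matrix
  raw_by_patient <- table(raw$obs[[patient_column]])
  kept_by_patient <- table(m$obs[[patient_column]])
  qsets <- suppressWarnings(
    qualifying_genes(m, patient_column, min_cells = min_cells)
  )
  row_tot <- Matrix::rowSums(m$counts)
  mean_by_patient <- tapply(row_tot, m$obs[[patient_column]], mean)
  patients <- sort(names(raw_by_patient))
  out <- purrr::map_dfr(patients, function(p) {
    kept <- if (p %in% names(kept_by_patient)) {
      as.integer(kept_by_patient[[p]])
    } else 0L
    tibble::tibble(
      patient = p,
      n_cells = as.integer(raw_by_patient[[p]]),
      n_filtered_cells = kept,
      mean_mutations_per_cell = if (kept > 0) {
        unname(mean_by_patient[[p]])
      } else NA_real_,
      n_mutated_genes = if (kept > 0) length(qsets[[p]]) else NA_integer_,
      note = if (kept > 0) "" else "no cells passed filtering"
    )
  })
  class(out) <- c("summary_report", class(out))
  out
}

#' Write a summary report as TSV and JSON
#'
#' @param report A `summary_report` tibble.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return Paths written, invisibly.
#' @export
write_summary_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  readr::write_tsv(report, tsv)
  json <- paste0(path_prefix, ".json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, json))
}

#' Export per-region gene lists
#'
#' @param counts Output of [venn_counts()].
#' @param path Output text file; one line per region: `region<TAB>gene,...`.
#' @return `path`, invisibly.
#' @export
write_venn_regions <- function(counts, path) {
  lines <- purrr::map_chr(seq_len(nrow(counts)), function(i) {
    paste0(counts$region[i], "\t", counts$count[i], "\t",
           paste(counts$genes[[i]], collapse = ","))
  })
  writeLines(c("region\tcount\tgenes", lines), path)
  invisible(path)
}
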