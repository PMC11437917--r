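#' Discover per-cell annotation files in a directory or ZIP archive
#'
#' Each annotation file corresponds to one cell; the cell id is the file base
#' name with the recognized extension chain stripped (`.txt`,
#' `.hg38_multianno.txt`, `.exonic_variant_function`, ...). Entries are
#' returned in lexicographic cell-id order so discovery is deterministic, and
#' a ZIP archive of the same files is equivalent to the unpacked directory.
#'
#' @param path A directory, or a `.zip` archive, of annotation files.
#' @return A tibble with columns `cell_id` and `file` (path to a readable
#'   file; for ZIP input, extracted under a session temp directory).
#' @export
discover_inputs <- function(path) {
  if (!file.exists(path)) stop("no such path: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- file.path(tempfile("mutumap_zip_"))
    dir.create(exdir, recursive = TRUE)
    files <- tryCatch(
      utils::unzip(path, exdir = exdir),
      error = function(e) stop("cannot read archive ", path, ": ",
                               conditionMessage(e)),
      warning = function(w) stop("cannot read archive ", path, ": ",
                                 conditionMessage(w))
    )
    files <- files[!dir.exists(files)]
  } else {
    stop("input must be a directory or a .zip archive: ", path)
  }
  files <- files[!grepl("^\\.", basename(files))]
  if (length(files) == 0) stop("no input cells found in ", path)
  out <- tibble::tibble(
    cell_id = strip_annovar_ext(basename(files)),
    file = files
  )
  if (anyDuplicated(out$cell_id)) {
    dup <- unique(out$cell_id[duplicated(out$cell_id)])
    stop("duplicate cell id(s) across input files: ",
         paste(dup, collapse = ", "))
  }
  dplyr::arrange(out, .data$cell_id)
}

strip_annovar_ext <- function(x) {
  x <- sub("\\.(hg\\d+|mm\\d+)_multianno\\.(txt|tsv)$", "", x)
  x <- sub("\\.exonic_variant_function$", "", x)
  sub("\\.(txt|tsv|csv)$", "", x)
}

MULTIANNO_GENE_COLS <- c("Gene.refGene", "Gene.knownGene", "Gene.ensGene", "Gene")
MULTIANNO_FUNC_COLS <- c("ExonicFunc.refGene", "ExonicFunc.knownGene",
                         "ExonicFunc.ensGene", "ExonicFunc")

canonical_func_class <- function(x) {
  x <- gsub("_", " ", trimws(x))
  known <- functional_classes()
  out <- known[match(tolower(x), tolower(known))]
  out[is.na(out)] <- "other"
  out
}

#' Parse one ANNOVAR-annotated variant table
#'
#' Auto-detects between the two common ANNOVAR output dialects: the
#' `*_multianno.txt` table (header row with `Gene.refGene` /
#' `ExonicFunc.refGene`-style columns) and the headerless
#' `exonic_variant_function` file (functional class in column 2, gene in
#' column 3, then chrom/start/end/ref/alt). Gene fields listing several genes
#' (separated by `;` or `,`) are kept as one record with all symbols.
#' Duplicate variants (same chrom, pos, ref, alt within the cell) are
#' deduplicated. Malformed rows are counted and skipped; if their fraction
#' exceeds `tolerance` parsing errors out.
#'
#' @param file Path to the annotation file.
#' @param cell_id Cell identifier attached to every record.
#' @param tolerance Maximum tolerated malformed-row fraction (default 0.2).
#' @param columns Optional manual column mapping, a named list with entries
#'   `gene`, `func`, `chrom`, `pos`, `ref`, `alt` (names or 1-based indices),
#'   bypassing dialect detection.
#' @return A tibble of annotated variant records: `cell_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene_symbols` (list column), `func_class`, with attributes
#'   `n_malformed` and `n_rows`. Zero parseable rows yields an empty tibble
#'   with a warning (the cell is retained downstream with zero counts).
#' @export
parse_annovar <- function(file, cell_id, tolerance = 0.2, columns = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(
    cell_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(),
    gene_symbols = list(), func_class = character()
  )
  if (length(lines) == 0) {
    warning("cell ", cell_id, ": no parseable rows; retained with zero counts")
    return(structure(empty, n_malformed = 0L, n_rows = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  has_header <- any(MULTIANNO_GENE_COLS %in% header) ||
    any(c("Chr", "Start", "Ref", "Alt") %in% header)

  if (!is.null(columns)) {
    idx_of <- function(key, flds) {
      v <- columns[[key]]
      if (is.null(v)) return(NA_integer_)
      if (is.numeric(v)) as.integer(v) else match(v, header)
    }
    body <- if (has_header) fields[-1] else fields
    map <- vapply(c("gene", "func", "chrom", "pos", "ref", "alt"),
                  idx_of, integer(1), flds = header)
  } else if (has_header) {
    body <- fields[-1]
    map <- c(
      gene = match(TRUE, header %in% MULTIANNO_GENE_COLS),
      func = match(TRUE, header %in% MULTIANNO_FUNC_COLS),
      chrom = match("Chr", header),
      pos = match("Start", header),
      ref = match("Ref", header),
      alt = match("Alt", header)
    )
  } else {
    # exonic_variant_function dialect: line-id, func class, "GENE:...,"
    # then chrom start end ref alt
    body <- fields
    map <- c(gene = 3L, func = 2L, chrom = 4L, pos = 5L, ref = 7L, alt = 8L)
  }
  if (is.na(map[["gene"]])) {
    warning("cell ", cell_id, ": no gene column found; retained with zero counts")
    return(structure(empty, n_malformed = length(body),
                     n_rows = length(body)))
  }

  pick <- function(flds, i) {
    if (is.na(i) || i > length(flds)) NA_character_ else flds[[i]]
  }
  rows <- purrr::map(body, function(flds) {
    gene_raw <- pick(flds, map[["gene"]])
    if (is.na(gene_raw) || !nzchar(trimws(gene_raw))) return(NULL)
    # exonic_variant_function gene field looks like "KRAS:NM_...:exon2:...,"
    if (!has_header && is.null(columns)) {
      parts <- strsplit(gene_raw, ",", fixed = TRUE)[[1]]
      genes <- unique(vapply(parts[nzchar(parts)],
                             function(p) strsplit(p, ":", fixed = TRUE)[[1]][1],
                             character(1), USE.NAMES = FALSE))
    } else {
      genes <- unique(trimws(strsplit(gene_raw, "[;,]")[[1]]))
    }
    genes <- genes[nzchar(genes) & genes != "NONE" & genes != "."]
    if (length(genes) == 0) return(NULL)
    pos_raw <- suppressWarnings(as.integer(pick(flds, map[["pos"]])))
    if (is.na(pos_raw) || pos_raw < 1) return(NULL)
    list(
      chrom = pick(flds, map[["chrom"]]),
      pos = pos_raw,
      ref = pick(flds, map[["ref"]]),
      alt = pick(flds, map[["alt"]]),
      gene_symbols = list(genes),
      func_class = canonical_func_class(pick(flds, map[["func"]]))
    )
  })
  ok <- !vapply(rows, is.null, logical(1))
  n_malformed <- sum(!ok)
  n_rows <- length(body)
  if (n_rows > 0 && n_malformed / n_rows > tolerance && n_malformed < n_rows) {
    stop("cell ", cell_id, ": ", n_malformed, "/", n_rows,
         " malformed rows exceeds tolerance ", tolerance)
  }
  if (!any(ok)) {
    warning("cell ", cell_id, ": no parseable rows; retained with zero counts")
    return(structure(empty, n_malformed = n_malformed, n_rows = n_rows))
  }
  rows <- rows[ok]
  rec <- tibble::tibble(
    cell_id = cell_id,
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    gene_symbols = lapply(rows, function(r) r$gene_symbols[[1]]),
    func_class = vapply(rows, `[[`, character(1), "func_class")
  )
  # one count per (cell, variant): drop duplicate chrom/pos/ref/alt rows
  rec <- rec[!duplicated(rec[c("chrom", "pos", "ref", "alt")]), , drop = FALSE]
  structure(rec, n_malformed = n_malformed, n_rows = n_rows)
}

#' Keep variant records of selected functional classes
#'
#' By default only non-synonymous SNVs are retained, the class the published
#' analyses keep; pass `keep_classes = functional_classes()` to keep every
#' record (the "keep all" mode used when too few genes survive filtering).
#'
#' @param records A tibble of variant records (from [parse_annovar()]).
#' @param keep_classes Character vector of functional classes to keep.
#' @return The records whose `func_class` is in `keep_classes`, order
#'   preserved.
#' @export
filter_functional <- function(records, keep_classes = "nonsynonymous SNV") {
  stopifnot(length(keep_classes) >= 1)
  records[records$func_class %in% keep_classes, , drop = FALSE]
}

#' Read the sample metadata table
#'
#' CSV or TSV with a header row; the delimiter is sniffed from the header
#' line. The first column becomes the sample/patient id; every remaining
#' column is classified `numeric` if all its non-missing values parse as
#' numbers, otherwise `categorical`. The categorical columns are the ones
#' offered for UMAP coloring and Venn grouping.
#'
#' @param path Path to the metadata file.
#' @return A tibble whose first column is named `sample_id`, with attribute
#'   `column_kinds` (named character vector, `"categorical"`/`"numeric"` per
#'   non-id column).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first)) stop("empty metadata file: ", path)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(df) == 0) stop("empty metadata file: ", path)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  kinds <- character(0)
  for (cn in setdiff(names(df), "sample_id")) {
    v <- df[[cn]]
    nonmiss <- v[!is.na(v) & nzchar(trimws(v))]
    num <- suppressWarnings(as.numeric(nonmiss))
    if (length(nonmiss) > 0 && !anyNA(num)) {
      df[[cn]] <- suppressWarnings(as.numeric(v))
      kinds[cn] <- "numeric"
    } else {
      kinds[cn] <- "categorical"
    }
  }
  attr(df, "column_kinds") <- kinds
  df
}

#' Categorical metadata columns of a table or mutation matrix
#'
#' @param x A metadata tibble from [read_metadata()] or a `mutation_matrix`.
#' @return Character vector of categorical column names (excluding ids).
#' @export
categorical_columns <- function(x) {
  if (inherits(x, "mutation_matrix")) x <- x$obs
  kinds <- attr(x, "column_kinds")
  if (!is.null(kinds)) return(names(kinds)[kinds == "categorical"])
  cols <- setdiff(names(x), "cell_id")
  cols[vapply(x[cols], function(v) !is.numeric(v), logical(1))]
}

#' Assemble the cells-by-genes mutation-count matrix
#'
#' Entry `[c, g]` is the number of retained variant records of cell `c`
#' annotated to gene `g`; a record listing k genes increments k entries. The
#' gene universe is the union over all cells. Cell metadata is joined by
#' matching the cell id against `sample_id` (exact match, or the cell id
#' prefixed by its sample id as in `SAMPLE_cellN`); unmatched cells are kept
#' with metadata set to the sentinel `"NA"` category and a warning (or an
#' error under `strict = TRUE`).
#'
#' @param records_by_cell Named list: cell id -> record tibble (possibly
#'   empty, giving an all-zero row).
#' @param metadata Metadata tibble from [read_metadata()], or `NULL`.
#' @param strict Error (rather than warn) on cells without a metadata match.
#' @return A `mutation_matrix`.
#' @export
count_matrix <- function(records_by_cell, metadata = NULL, strict = FALSE) {
  ids <- names(records_by_cell)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("records_by_cell must be uniquely named by cell id")
  }
  ids <- sort(ids)
  pairs <- purrr::map_dfr(ids, function(cid) {
    rec <- records_by_cell[[cid]]
    if (is.null(rec) || nrow(rec) == 0) {
      return(tibble::tibble(cell_id = character(), gene = character()))
    }
    tibble::tibble(
      cell_id = cid,
      gene = unlist(rec$gene_symbols, use.names = FALSE)
    )
  })
  if (nrow(pairs) == 0) stop("no variant records in any cell")
  genes <- sort(unique(pairs$gene))
  counts <- Matrix::sparseMatrix(
    i = match(pairs$cell_id, ids),
    j = match(pairs$gene, genes),
    x = 1,
    dims = c(length(ids), length(genes)),
    dimnames = list(ids, genes)
  )
  obs <- tibble::tibble(cell_id = ids)
  if (!is.null(metadata)) {
    obs$sample_id <- match_sample_id(ids, metadata$sample_id)
    unmatched <- ids[is.na(obs$sample_id)]
    if (length(unmatched)) {
      msg <- paste0(length(unmatched), " cell(s) without metadata match: ",
                    paste(utils::head(unmatched, 5), collapse = ", "))
      if (strict) stop(msg)
      warning(msg, "; metadata set to \"NA\"")
    }
    obs <- dplyr::left_join(obs, metadata, by = "sample_id")
    kinds <- attr(metadata, "column_kinds")
    for (cn in names(kinds)[kinds == "categorical"]) {
      obs[[cn]][is.na(obs[[cn]])] <- "NA"
    }
    obs$sample_id[is.na(obs$sample_id)] <- "NA"
  }
  mutation_matrix(counts, obs = obs)
}

match_sample_id <- function(cell_ids, sample_ids) {
  out <- sample_ids[match(cell_ids, sample_ids)]
  miss <- is.na(out)
  if (any(miss)) {
    # longest sample_id that prefixes the cell id (e.g. P01_cell003 -> P01)
    ord <- order(nchar(sample_ids), decreasing = TRUE)
    for (sid in sample_ids[ord]) {
      hit <- miss & startsWith(cell_ids, paste0(sid, "_"))
      out[hit] <- sid
      miss <- is.na(out)
    }
  }
  out
}

#' Convert annotation files plus metadata into a mutation matrix
#'
#' The full ingest path: discover per-cell files (directory or ZIP), parse
#' each ANNOVAR table, keep the configured functional classes, and assemble
#' the count matrix joined with metadata.
#'
#' @param input Directory or ZIP of per-cell annotation files.
#' @param metadata Path to the metadata CSV/TSV, or `NULL`.
#' @param config A [pipeline_config()].
#' @param strict Passed to [count_matrix()].
#' @return A `mutation_matrix`.
#' @export
ingest_variants <- function(input, metadata = NULL,
                            config = pipeline_config(), strict = FALSE) {
  inputs <- discover_inputs(input)
  meta <- if (is.null(metadata)) NULL else read_metadata(metadata)
  records <- purrr::map(seq_len(nrow(inputs)), function(i) {
    rec <- parse_annovar(inputs$file[i], inputs$cell_id[i],
                         tolerance = config$malformed_tolerance)
    filter_functional(rec, keep_classes = config$keep_classes)
  })
  names(records) <- inputs$cell_id
  count_matrix(records, metadata = meta, strict = strict)
}
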