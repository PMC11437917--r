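#' Specification of a synthetic single-cell mutation dataset
#'
#' Describes planted group structure: `n_groups` groups of cells, each group
#' mutating its own disjoint signature gene set on top of a low background
#' mutation rate shared by all genes. The defaults (signature of 60 genes hit
#' at rate 0.8 per member cell, background rate 0.02) give the group-separable
#' structure that the pipeline is designed to recover.
#'
#' @param n_groups Number of groups.
#' @param cells_per_group Cells per group.
#' @param signature_size Signature genes per group (default 60).
#' @param n_background_genes Genes outside every signature (default 400).
#' @param per_cell_signature_rate P(signature gene mutated in a member cell)
#'   (default 0.8).
#' @param background_rate P(background-model mutation of any gene in any
#'   cell) (default 0.02).
#' @param patients_per_group Patients each group's cells are split across
#'   (default 2).
#' @param synonymous_fraction Fraction of additional synonymous rows mixed in
#'   per file, exercising the functional-class filter (default 0.3 of the
#'   non-synonymous row count).
#' @param seed Integer seed; the fixture is fully determined by it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_groups = 3L, cells_per_group = 20L,
                         signature_size = 60L, n_background_genes = 400L,
                         per_cell_signature_rate = 0.8,
                         background_rate = 0.02,
                         patients_per_group = 2L,
                         synonymous_fraction = 0.3,
                         seed = 0L) {
  stopifnot(
    n_groups >= 1, cells_per_group >= 1, signature_size >= 1,
    n_background_genes >= 0,
    per_cell_signature_rate >= 0, per_cell_signature_rate <= 1,
    background_rate >= 0, background_rate <= 1,
    patients_per_group >= 1, synonymous_fraction >= 0
  )
  structure(list(
    n_groups = as.integer(n_groups),
    cells_per_group = as.integer(cells_per_group),
    signature_size = as.integer(signature_size),
    n_background_genes = as.integer(n_background_genes),
    per_cell_signature_rate = per_cell_signature_rate,
    background_rate = background_rate,
    patients_per_group = as.integer(patients_per_group),
    synonymous_fraction = synonymous_fraction,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic ANNOVAR-style dataset with planted groups
#'
#' Writes one tab-separated multianno-dialect annotation file per cell
#' (columns Chr, Start, End, Ref, Alt, Func.refGene, Gene.refGene,
#' ExonicFunc.refGene), a metadata CSV whose first column is the patient id
#' with `group` and `stage` categorical columns plus a numeric column, and a
#' ground-truth TSV mapping each cell to its planted group. Positions and
#' alleles are synthetic (not tied to a genome build); gene symbols are
#' `G0001`, `G0002`, .... Each mutated gene contributes one non-synonymous
#' SNV row, and synonymous rows are mixed in to exercise functional-class
#' filtering. Output is fully determined by `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `dir` (annotation-file subdirectory),
#'   `metadata` (metadata CSV path), `truth` (ground-truth TSV path),
#'   `truth_table` (tibble cell_id/patient/group), `signatures` (named list of
#'   signature gene sets).
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", out_dir)
  cells_dir <- file.path(out_dir, "cells")
  if (!dir.exists(cells_dir) && !dir.create(cells_dir)) {
    stop("cannot create output directory ", cells_dir)
  }

  set.seed(spec$seed)
  n_genes <- spec$n_groups * spec$signature_size + spec$n_background_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  sig_idx <- split(
    seq_len(spec$n_groups * spec$signature_size),
    rep(seq_len(spec$n_groups), each = spec$signature_size)
  )
  signatures <- lapply(sig_idx, function(i) genes[i])
  names(signatures) <- paste0("group", seq_len(spec$n_groups))
  gene_pos <- seq_len(n_genes) * 10000L # one locus block per gene

  truth <- tidyr::expand_grid(
    group = seq_len(spec$n_groups),
    cell = seq_len(spec$cells_per_group)
  )
  truth$patient <- sprintf(
    "P%02d", (truth$group - 1L) * spec$patients_per_group +
      ((truth$cell - 1L) %% spec$patients_per_group) + 1L
  )
  truth$cell_id <- sprintf("%s_cell%03d", truth$patient, truth$cell)
  truth$group <- paste0("group", truth$group)

  for (i in seq_len(nrow(truth))) {
    g <- match(truth$group[i], names(signatures))
    mutated <- logical(n_genes)
    mutated[sig_idx[[g]]] <- stats::runif(spec$signature_size) <
      spec$per_cell_signature_rate
    bg <- stats::runif(n_genes) < spec$background_rate
    mutated <- mutated | bg
    idx <- which(mutated)
    n_syn <- ceiling(length(idx) * spec$synonymous_fraction)
    syn_idx <- if (n_syn > 0) {
      sample(n_genes, min(n_syn, n_genes))
    } else integer(0)
    rows <- make_annovar_rows(idx, syn_idx, genes, gene_pos)
    writeLines(rows, file.path(cells_dir, paste0(truth$cell_id[i], ".txt")))
  }

  patients <- unique(truth[, c("patient", "group")])
  meta <- tibble::tibble(
    patient = patients$patient,
    group = patients$group,
    stage = rep_len(c("I", "II", "III"), nrow(patients)),
    n_cells = as.integer(table(truth$patient)[patients$patient])
  )
  meta_path <- file.path(out_dir, "metadata.csv")
  readr::write_csv(meta, meta_path)

  truth_tbl <- tibble::as_tibble(truth[, c("cell_id", "patient", "group")])
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  readr::write_tsv(truth_tbl, truth_path)

  invisible(list(
    dir = cells_dir, metadata = meta_path, truth = truth_path,
    truth_table = truth_tbl, signatures = signatures
  ))
}

make_annovar_rows <- function(nonsyn_idx, syn_idx, genes, gene_pos) {
  header <- paste(
    c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene", "Gene.refGene",
      "ExonicFunc.refGene"),
    collapse = "\t"
  )
  row_for <- function(i, func) {
    pos <- gene_pos[i] + sample.int(5000L, 1L)
    ref <- sample(BASES, 1L)
    alt <- sample(setdiff(BASES, ref), 1L)
    paste(
      paste0("chr", 1L + (i %% 22L)), pos, pos, ref, alt,
      "exonic", genes[i], func,
      sep = "\t"
    )
  }
  c(
    header,
    vapply(nonsyn_idx, row_for, character(1), func = "nonsynonymous SNV"),
    vapply(syn_idx, row_for, character(1), func = "synonymous SNV")
  )
}

#' Zip a fixture's annotation files
#'
#' Writes a stored (uncompressed) ZIP archive of the per-cell files, for
#' testing archive/directory input equivalence. Entries are added in sorted
#' name order so the archive is deterministic.
#'
#' @param cells_dir Directory of per-cell annotation files.
#' @param zip_path Output `.zip` path.
#' @return `zip_path`, invisibly.
#' @export
zip_fixture <- function(cells_dir, zip_path) {
  files <- sort(list.files(cells_dir, full.names = FALSE))
  con <- file(zip_path, "wb")
  on.exit(close(con), add = TRUE)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(files))
  infos <- vector("list", length(files))
  pos <- 0L
  for (i in seq_along(files)) {
    data <- readBin(file.path(cells_dir, files[i]), "raw",
                    file.size(file.path(cells_dir, files[i])))
    name <- charToRaw(files[i])
    crc <- crc32(data)
    offsets[i] <- pos
    u32(0x04034b50) # local file header
    u16(20); u16(0); u16(0) # version, flags, method = stored
    u16(0); u16(0) # fixed dos time/date for determinism
    u32(crc); u32(length(data)); u32(length(data))
    u16(length(name)); u16(0)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
    infos[[i]] <- list(name = name, crc = crc, size = length(data))
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    fi <- infos[[i]]
    u32(0x02014b50) # central directory header
    u16(20); u16(20); u16(0); u16(0)
    u16(0); u16(0)
    u32(fi$crc); u32(fi$size); u32(fi$size)
    u16(length(fi$name)); u16(0); u16(0)
    u16(0); u16(0); u32(0)
    u32(offsets[i])
    writeBin(fi$name, con)
    pos <- pos + 46L + length(fi$name)
  }
  u32(0x06054b50) # end of central directory
  u16(0); u16(0)
  u16(length(files)); u16(length(files))
  u32(pos - cd_start); u32(cd_start)
  u16(0)
  invisible(zip_path)
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- vapply(0:255, function(n) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1), -306674912L) # 0xEDB88320
          } else {
            bitwShiftR(c, 1)
          }
        }
        c
      }, integer(1))
      tab <<- t
    }
    tab
  }
})

# bitwShiftR treats its argument as an unsigned 32-bit value, which is
# exactly the logical shift the CRC update needs
crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(data)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L) + 1L
    crc <- bitwXor(tab[idx], bitwShiftR(crc, 8))
  }
  bitwXor(crc, -1L)
}
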