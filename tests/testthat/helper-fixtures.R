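# Shared helpers: small fixtures built in code and independent oracles.

# A deterministic toy count matrix with known per-gene/per-cell support.
toy_matrix <- function() {
  counts <- rbind(
    c1 = c(gA = 2, gB = 1, gC = 0, gD = 1),
    c2 = c(gA = 1, gB = 0, gC = 0, gD = 2),
    c3 = c(gA = 3, gB = 2, gC = 1, gD = 0),
    c4 = c(gA = 0, gB = 1, gC = 0, gD = 1)
  )
  obs <- tibble::tibble(
    sample_id = c("P1", "P1", "P2", "P2"),
    group = c("X", "X", "Y", "Y")
  )
  mutation_matrix(counts, obs = obs)
}

small_fixture_spec <- function(seed) {
  fixture_spec(
    n_groups = 2L, cells_per_group = 5L, signature_size = 10L,
    n_background_genes = 30L, per_cell_signature_rate = 0.8,
    background_rate = 0.05, seed = seed
  )
}

# Independent line-by-line recount of raw multianno fixture files: read with
# base R, keep rows of the given functional classes, deduplicate variants,
# split multi-gene fields, tabulate (cell, gene) pairs.
brute_recount <- function(cells_dir, keep_classes = "nonsynonymous SNV") {
  files <- sort(list.files(cells_dir, full.names = TRUE))
  pair_list <- list()
  for (f in files) {
    cid <- sub("\\.txt$", "", basename(f))
    tab <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
    tab <- tab[!duplicated(tab[, c("Chr", "Start", "Ref", "Alt")]), ,
               drop = FALSE]
    tab <- tab[tab$ExonicFunc.refGene %in% keep_classes, , drop = FALSE]
    if (nrow(tab) == 0) next
    genes <- unlist(lapply(tab$Gene.refGene, function(g) {
      unique(strsplit(g, "[;,]")[[1]])
    }))
    pair_list[[cid]] <- data.frame(cell = cid, gene = genes)
  }
  pairs <- do.call(rbind, pair_list)
  cells <- sort(sub("\\.txt$", "", basename(files)))
  genes <- sort(unique(pairs$gene))
  out <- matrix(0L, length(cells), length(genes),
                dimnames = list(cells, genes))
  for (i in seq_len(nrow(pairs))) {
    out[pairs$cell[i], pairs$gene[i]] <- out[pairs$cell[i], pairs$gene[i]] + 1L
  }
  out
}

# Two well-separated Gaussian blobs in 5 dimensions.
two_blob_values <- function(n_per = 20, sep = 50, seed = 42) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n_per * 5), n_per),
    matrix(stats::rnorm(n_per * 5, mean = sep), n_per)
  )
  rownames(x) <- sprintf("cell%02d", seq_len(2 * n_per))
  colnames(x) <- paste0("f", 1:5)
  x
}

# Block-diagonal graph of two disconnected cliques.
two_clique_graph <- function(n_per = 10) {
  n <- 2 * n_per
  g <- matrix(0, n, n)
  g[seq_len(n_per), seq_len(n_per)] <- 1
  g[(n_per + 1):n, (n_per + 1):n] <- 1
  diag(g) <- 0
  rownames(g) <- colnames(g) <- sprintf("v%02d", seq_len(n))
  Matrix::Matrix(g, sparse = TRUE)
}

truth_aligned <- function(fx, ids) {
  truth <- utils::read.delim(fx$truth, stringsAsFactors = FALSE)
  truth$group[match(ids, truth$cell_id)]
}

write_lines_file <- function(lines, dir, name) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

multianno_header <- paste(
  c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene", "Gene.refGene",
    "ExonicFunc.refGene"),
  collapse = "\t"
)

multianno_row <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                          gene = "KRAS", func = "nonsynonymous SNV") {
  paste(chrom, pos, pos, ref, alt, "exonic", gene, func, sep = "\t")
}
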