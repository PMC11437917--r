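test_that("discover_inputs lists cells deterministically and strips extensions", {
  d <- withr::local_tempdir()
  write_lines_file(c(multianno_header, multianno_row()), d, "c2.txt")
  write_lines_file(c(multianno_header, multianno_row()), d, "c1.txt")
  write_lines_file(c(multianno_header, multianno_row()), d,
                   "c3.hg38_multianno.txt")
  got <- discover_inputs(d)
  expect_equal(got$cell_id, c("c1", "c2", "c3"))

  empty <- withr::local_tempdir()
  expect_error(discover_inputs(empty), "no input cells")
  expect_error(discover_inputs(file.path(empty, "nope")), "no such path")
})

test_that("ZIP archives and directories yield the same inputs", {
  d <- withr::local_tempdir()
  write_lines_file(c(multianno_header, multianno_row(gene = "EGFR")), d, "a.txt")
  write_lines_file(c(multianno_header, multianno_row(gene = "TP53")), d, "b.txt")
  z <- file.path(withr::local_tempdir(), "cells.zip")
  zip_fixture(d, z)
  from_dir <- discover_inputs(d)
  from_zip <- discover_inputs(z)
  expect_equal(from_zip$cell_id, from_dir$cell_id)
  expect_equal(
    lapply(from_zip$file, readLines),
    lapply(from_dir$file, readLines)
  )
  expect_error(discover_inputs(file.path(d, "missing.zip")), "no such path")
})

test_that("parse_annovar handles both dialects, multi-gene fields and duplicates", {
  d <- withr::local_tempdir()
  f <- write_lines_file(c(
    multianno_header,
    multianno_row(pos = 10, gene = "KRAS"),
    multianno_row(pos = 20, gene = "GENE1;GENE2"),
    multianno_row(pos = 20, gene = "GENE1;GENE2"), # duplicate variant
    multianno_row(pos = 30, gene = "X", func = "synonymous SNV")
  ), d, "cell.txt")
  rec <- parse_annovar(f, "cell")
  expect_equal(nrow(rec), 3) # duplicate removed
  expect_equal(rec$gene_symbols[[1]], "KRAS")
  expect_equal(rec$gene_symbols[[2]], c("GENE1", "GENE2"))
  expect_equal(rec$func_class, c("nonsynonymous SNV", "nonsynonymous SNV",
                                 "synonymous SNV"))
  expect_true(all(rec$pos >= 1))

  # headerless exonic_variant_function dialect: class in col 2, gene in col 3
  f2 <- write_lines_file(c(
    paste("line1", "nonsynonymous SNV",
          "KRAS:NM_004985:exon2:c.G35A:p.G12D,",
          "chr12", "25398284", "25398284", "G", "A", sep = "\t"),
    paste("line2", "synonymous SNV", "TP53:NM_000546:exon4:c.C100T,",
          "chr17", "7579472", "7579472", "C", "T", sep = "\t")
  ), d, "cell2.exonic_variant_function")
  rec2 <- parse_annovar(f2, "cell2")
  expect_equal(rec2$gene_symbols, list("KRAS", "TP53"))
  expect_equal(rec2$func_class, c("nonsynonymous SNV", "synonymous SNV"))
})

test_that("malformed rows are tolerated up to the configured fraction", {
  d <- withr::local_tempdir()
  rows <- c(multianno_header,
            multianno_row(pos = 10),
            paste("chr1", 20, 20, "A", "T", "exonic", "", "nonsynonymous SNV",
                  sep = "\t")) # missing gene
  f <- write_lines_file(rows, d, "c.txt")
  rec <- parse_annovar(f, "c", tolerance = 0.6)
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_malformed"), 1L)
  expect_error(parse_annovar(f, "c", tolerance = 0.1), "tolerance")

  f0 <- write_lines_file(multianno_header, d, "z.txt")
  expect_warning(rec0 <- parse_annovar(f0, "z"), "zero|no parseable")
  expect_equal(nrow(rec0), 0)
})

test_that("filter_functional keeps the requested classes in order", {
  rec <- tibble::tibble(
    cell_id = "c", chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
    gene_symbols = list("g1", "g2", "g3"),
    func_class = c("nonsynonymous SNV", "synonymous SNV", "stopgain")
  )
  expect_equal(filter_functional(rec)$gene_symbols, list("g1"))
  expect_equal(filter_functional(rec, functional_classes()), rec)
  empty <- rec[0, ]
  expect_equal(nrow(filter_functional(empty)), 0)
})

test_that("read_metadata infers column kinds and sniffs the delimiter", {
  d <- withr::local_tempdir()
  csv <- write_lines_file(c(
    "id,type,stage,n_cells",
    "P1,AC,I,10",
    "P2,SCC,II,20"
  ), d, "meta.csv")
  meta <- read_metadata(csv)
  expect_equal(names(meta)[1], "sample_id")
  expect_equal(attr(meta, "column_kinds"),
               c(type = "categorical", stage = "categorical",
                 n_cells = "numeric"))
  expect_equal(categorical_columns(meta), c("type", "stage"))

  tsv <- write_lines_file(c(
    "id\ttype\tstage\tn_cells",
    "P1\tAC\tI\t10",
    "P2\tSCC\tII\t20"
  ), d, "meta.tsv")
  meta_tsv <- read_metadata(tsv)
  expect_equal(as.data.frame(meta_tsv), as.data.frame(meta))
  expect_equal(attr(meta_tsv, "column_kinds"), attr(meta, "column_kinds"))

  mixed <- write_lines_file(c("id,v", "P1,1", "P2,2", "P3,x"), d, "mixed.csv")
  expect_equal(attr(read_metadata(mixed), "column_kinds"),
               c(v = "categorical"))

  dup <- write_lines_file(c("id,v", "P1,1", "P1,2"), d, "dup.csv")
  expect_error(read_metadata(dup), "duplicate sample_id")
  expect_error(read_metadata(write_lines_file(character(0), d, "e.csv")),
               "empty")
})

test_that("count_matrix counts records per gene with multi-gene increments", {
  recs <- list(
    c1 = tibble::tibble(
      cell_id = "c1", chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
      gene_symbols = list("A", "A", "B"),
      func_class = "nonsynonymous SNV"
    ),
    c2 = tibble::tibble(
      cell_id = "c2", chrom = "chr1", pos = 1L, ref = "A", alt = "T",
      gene_symbols = list(c("A", "B")),
      func_class = "nonsynonymous SNV"
    ),
    c3 = tibble::tibble(
      cell_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene_symbols = list(),
      func_class = character()
    )
  )
  m <- count_matrix(recs)
  expect_equal(as.matrix(m$counts),
               matrix(c(2, 1, 0, 1, 1, 0), 3,
                      dimnames = list(c("c1", "c2", "c3"), c("A", "B"))))
  # total sum = number of retained (record, gene) pairs
  expect_equal(sum(m$counts), 3 + 2)

  bad <- recs[c(1, 1)]
  expect_error(count_matrix(bad), "uniquely named")
})

test_that("cells missing from metadata get the NA sentinel (or error in strict mode)", {
  d <- withr::local_tempdir()
  write_lines_file(c(multianno_header, multianno_row()), d, "P1_cell1.txt")
  write_lines_file(c(multianno_header, multianno_row(gene = "EGFR")), d,
                   "ORPHAN_cell1.txt")
  meta_path <- write_lines_file(c("id,type", "P1,AC"),
                                withr::local_tempdir(), "meta.csv")
  expect_warning(
    m <- ingest_variants(d2 <- d, meta_path),
    "without metadata match"
  )
  orphan <- m$obs[m$obs$cell_id == "ORPHAN_cell1", ]
  expect_equal(orphan$sample_id, "NA")
  expect_equal(orphan$type, "NA")
  expect_error(
    suppressWarnings(ingest_variants(d, meta_path, strict = TRUE)),
    "without metadata match"
  )
})

test_that("assembled counts equal an independent brute-force recount", {
  out <- withr::local_tempdir()
  fx <- generate_fixture(small_fixture_spec(seed = 7), out)
  m <- ingest_variants(fx$dir, fx$metadata)
  oracle <- brute_recount(fx$dir)
  expect_identical(
    as.matrix(m$counts)[rownames(oracle), colnames(oracle)],
    oracle * 1.0
  )
  # column-sum conservation against the oracle total
  expect_equal(sum(m$counts), sum(oracle))
})

test_that("input discovery order does not affect the assembled matrix", {
  out <- withr::local_tempdir()
  fx <- generate_fixture(small_fixture_spec(seed = 11), out)
  inputs <- discover_inputs(fx$dir)
  meta <- read_metadata(fx$metadata)
  recs <- lapply(seq_len(nrow(inputs)), function(i) {
    filter_functional(parse_annovar(inputs$file[i], inputs$cell_id[i]))
  })
  names(recs) <- inputs$cell_id
  m1 <- count_matrix(recs, meta)
  set.seed(1)
  perm <- sample(length(recs))
  m2 <- count_matrix(recs[perm], meta)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_identical(m1$obs, m2$obs)
})
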