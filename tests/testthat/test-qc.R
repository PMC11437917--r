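test_that("gene filter keeps genes mutated in at least k cells", {
  # supports: gA in 3 cells, gB in 3, gC in 1, gD in 3 (toy matrix)
  m <- toy_matrix()
  support <- Matrix::colSums(m$counts > 0)
  k <- 3
  out <- filter_genes_min_cells(m, k)
  expect_setequal(gene_ids(out), names(support)[support >= k])
  expect_true(min(Matrix::colSums(out$counts > 0)) >= k)
  expect_equal(attr(out, "removed"), names(support)[support < k])

  expect_identical(as.matrix(filter_genes_min_cells(m, 1)$counts),
                   as.matrix(m$counts))
  expect_error(filter_genes_min_cells(m, nrow(m$counts) + 1), "all genes")
})

test_that("cell filter boundary is inclusive: 'fewer than k' removed, k kept", {
  counts <- matrix(0L, 2, 30,
                   dimnames = list(c("c1", "c2"), paste0("g", 1:30)))
  counts["c1", 1:30] <- 1L
  counts["c2", 1:29] <- 1L
  m <- mutation_matrix(counts)
  out <- filter_cells_min_genes(m, 30)
  expect_equal(cell_ids(out), "c1")
  expect_equal(attr(out, "removed"), "c2")
  expect_error(filter_cells_min_genes(m, 31), "all cells")
  m2 <- toy_matrix()
  expect_identical(as.matrix(filter_cells_min_genes(m2, 1)$counts),
                   as.matrix(m2$counts))
})

test_that("upper-percentile cut uses linear interpolation and strict exceedance", {
  # per-cell mutated-gene counts 30, 40, 50, 60, 1000
  build <- function(gene_counts) {
    n_genes <- max(gene_counts)
    counts <- matrix(0L, length(gene_counts), n_genes,
                     dimnames = list(paste0("c", seq_along(gene_counts)),
                                     paste0("g", seq_len(n_genes))))
    for (i in seq_along(gene_counts)) counts[i, seq_len(gene_counts[i])] <- 1L
    mutation_matrix(counts)
  }
  m <- build(c(30, 40, 50, 60, 1000))
  out <- filter_cells_upper_percentile(m, 98)
  expect_equal(attr(out, "threshold"), 924.8)
  expect_equal(attr(out, "removed"), "c5")
  expect_equal(nrow(out$counts), 4)

  expect_equal(nrow(filter_cells_upper_percentile(m, 100)$counts), 5)
  m_eq <- build(c(10, 10, 10))
  expect_equal(nrow(filter_cells_upper_percentile(m_eq, 98)$counts), 3)
})

test_that("normalization scales every cell to the median target", {
  counts <- matrix(c(4, 6, 8, 12), 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  m <- mutation_matrix(counts) # totals 10 and 20, median 15
  norm <- normalize_total(m)
  expect_equal(norm$target, 15)
  expect_equal(as.matrix(norm$values),
               rbind(c1 = c(4, 6) * 1.5, c2 = c(8, 12) * 0.75),
               ignore_attr = TRUE)
  expect_equal(unname(Matrix::rowSums(norm$values)), c(15, 15))

  # equal totals: identity
  counts2 <- matrix(c(1, 9, 5, 5), 2, byrow = TRUE,
                    dimnames = list(c("c1", "c2"), c("g1", "g2")))
  m2 <- mutation_matrix(counts2)
  expect_equal(as.matrix(normalize_total(m2)$values), as.matrix(m2$counts),
               ignore_attr = TRUE)

  # single cell: median is its own total
  m3 <- mutation_matrix(matrix(c(2L, 3L), 1, dimnames = list("c", c("a", "b"))))
  expect_equal(as.matrix(normalize_total(m3)$values),
               as.matrix(m3$counts), ignore_attr = TRUE)
})

test_that("log1p transform is exact at anchors and order preserving", {
  expect_equal(as.numeric(log1p_transform(matrix(0, 1, 1))), 0)
  expect_equal(as.numeric(log1p_transform(matrix(exp(1) - 1, 1, 1))), 1)
  set.seed(5)
  v <- matrix(stats::rexp(100), 10)
  lt <- log1p_transform(v)
  expect_equal(order(v), order(lt))
  expect_error(log1p_transform(matrix(-1, 1, 1)), "non-negative")
  sp <- Matrix::rsparsematrix(20, 10, 0.3, rand.x = function(n) stats::rexp(n))
  expect_equal(as.matrix(log1p_transform(sp)), log1p(as.matrix(sp)))
})

test_that("HVG selection saturates, ranks an inflated gene first and is stable under ties", {
  set.seed(9)
  values <- log1p(matrix(stats::rpois(40 * 50, 3), 40, 50))
  colnames(values) <- sprintf("g%02d", 1:50)
  rownames(values) <- sprintf("c%02d", 1:40)
  sel_all <- select_hvg(values, n = 100)
  expect_setequal(sel_all$genes, colnames(values))

  # same mean as a typical gene (so it stays in a populated mean bin) but
  # vastly inflated variance; few bins so each holds enough genes for a
  # meaningful within-bin z-score at this small gene count
  inflated <- values
  inflated[, "g25"] <- log1p(c(rep(0, 39), 120))
  sel <- select_hvg(inflated, n = 5, n_bins = 4)
  top <- sel$table$gene_id[which.max(sel$table$dispersion_norm)]
  expect_equal(top, "g25")
  expect_true("g25" %in% sel$genes)

  # exact ties: duplicated gene columns; stable input order breaks them
  tied <- values[, c(1, 1, 2, 2, 3, 3)]
  colnames(tied) <- paste0("t", 1:6)
  sel_t <- select_hvg(tied, n = 3)
  ord <- order(-sel_t$table$dispersion_norm)
  expect_equal(sel_t$genes, sort(colnames(tied)[ord[1:3]]))
  expect_error(select_hvg(values[, 1, drop = FALSE], 1), "at least 2")
})

test_that("regress-out residuals are orthogonal to totals and match lm", {
  set.seed(21)
  n <- 30
  totals <- stats::runif(n, 20, 100)
  values <- cbind(
    linear = 2 * totals + 5, # perfectly linear gene
    noise = stats::rnorm(n),
    mixed = 0.5 * totals + stats::rnorm(n)
  )
  rownames(values) <- paste0("c", 1:n)
  res <- regress_out_total(values, totals)
  expect_lt(max(abs(res[, "linear"])), 1e-9)
  for (g in colnames(values)) {
    if (stats::sd(res[, g]) > 1e-10) { # correlation undefined for a perfect fit
      expect_lt(abs(stats::cor(res[, g], totals)), 1e-8)
    }
    oracle <- stats::residuals(stats::lm(values[, g] ~ totals))
    expect_equal(unname(res[, g]), unname(oracle), tolerance = 1e-10)
  }
  expect_warning(regress_out_total(values, rep(5, n)), "constant covariate")
})

test_that("the preprocessing chain telescopes and is deterministic", {
  out <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(n_groups = 2, cells_per_group = 10,
                                      signature_size = 40,
                                      n_background_genes = 100, seed = 4),
                         out)
  m <- ingest_variants(fx$dir, fx$metadata)
  cfg <- pipeline_config(min_genes_per_cell = 10, n_hvg = 50)
  qc1 <- qc_preprocess(m, cfg)
  qc2 <- qc_preprocess(m, cfg)
  expect_identical(qc1$values, qc2$values)
  expect_identical(qc1$report$n_cells_after, qc2$report$n_cells_after)

  rep <- qc1$report
  for (i in seq_len(nrow(rep) - 1)) {
    expect_equal(rep$n_cells_after[i], rep$n_cells_before[i + 1])
    expect_equal(rep$n_genes_after[i], rep$n_genes_before[i + 1])
  }
  expect_equal(rep$n_cells_after[nrow(rep)], nrow(qc1$matrix$counts))
  expect_equal(rep$n_genes_after[nrow(rep)], ncol(qc1$matrix$counts))
  # removed cell lists are disjoint across cell-removing steps
  cells_removed <- rep$removed[rep$step != "filter_genes_min_cells"]
  expect_equal(anyDuplicated(unlist(cells_removed)), 0)

  # per-cell totals after normalization all equal the median target
  norm <- normalize_total(qc1$matrix, cfg$target_sum)
  expect_equal(unname(Matrix::rowSums(norm$values)),
               rep(norm$target, nrow(qc1$matrix$counts)),
               tolerance = 1e-9)
})

test_that("filter report serializes to TSV and JSON", {
  m <- toy_matrix()
  qc <- qc_preprocess(m, pipeline_config(min_cells_per_gene = 1,
                                         min_genes_per_cell = 1,
                                         n_hvg = 4, n_neighbors = 2))
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- write_filter_report(tidy(qc), prefix)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[2])
  expect_equal(length(back), nrow(qc$report))
})
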