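test_that("qualifying genes require support in at least min_cells per patient", {
  # P1: gA in cells c1,c2 (2 cells), gB in c1 only
  # P2: gA in c3, gB in c3,c4, gC in c3, gD in c4
  m <- toy_matrix()
  qs <- qualifying_genes(m, "sample_id", min_cells = 2)
  expect_equal(qs$P1, c("gA", "gD"))
  expect_equal(qs$P2, "gB")

  qs1 <- qualifying_genes(m, "sample_id", min_cells = 1)
  # min_cells = 1: every nonzero gene per patient
  expect_setequal(qs1$P1, c("gA", "gB", "gD"))

  # monotonicity: raising min_cells never grows a set
  for (p in names(qs)) expect_true(all(qs[[p]] %in% qs1[[p]]))
  qs3 <- suppressWarnings(qualifying_genes(m, "sample_id", min_cells = 3))
  for (p in names(qs3)) expect_true(all(qs3[[p]] %in% qs[[p]]))

  expect_error(qualifying_genes(m, "nope"), "unknown column")
})

test_that("patients with too few cells get empty sets with a warning", {
  counts <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  obs <- tibble::tibble(sample_id = c("P1", "P1", "P2"))
  m <- mutation_matrix(counts, obs = obs)
  expect_warning(qs <- qualifying_genes(m, "sample_id", 2), "fewer than 2")
  expect_equal(qs$P2, character(0))
  expect_setequal(qs$P1, c("g1", "g2"))
})

test_that("group sets are unions of member patients' sets", {
  per_patient <- list(P1 = c("A", "B"), P2 = c("B"), P3 = c("B", "C"),
                      P4 = c("C"))
  obs <- tibble::tibble(
    cell_id = paste0("c", 1:4),
    sample_id = c("P1", "P2", "P3", "P4"),
    grp = c("X", "X", "Y", "Y")
  )
  coll <- group_sets(per_patient, obs, "grp")
  expect_equal(coll$sets$X, c("A", "B"))
  expect_equal(coll$sets$Y, c("B", "C"))

  single <- group_sets(per_patient, dplyr::mutate(obs, grp = "only"), "grp")
  expect_equal(length(single$sets), 1)

  obs5 <- tibble::tibble(
    cell_id = paste0("c", 1:5), sample_id = paste0("P", 1:5),
    grp = paste0("g", 1:5)
  )
  expect_error(group_sets(c(per_patient, list(P5 = "Z")), obs5, "grp"),
               "at most 4")
})

test_that("venn region counts are exclusive and sum to the union", {
  vc <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(vc$count[vc$region == "A"], 1)
  expect_equal(vc$count[vc$region == "B"], 1)
  expect_equal(vc$count[vc$region == "A&B"], 1)
  expect_equal(vc$genes[[which(vc$region == "A&B")]], "b")

  disjoint <- list(w = "a", x = "b", y = "c", z = "d")
  vd <- venn_counts(disjoint)
  expect_equal(nrow(vd), 15)
  inter <- vd[lengths(vd$sets) > 1, ]
  expect_true(all(inter$count == 0))
  expect_equal(sum(vd$count), 4)

  same <- venn_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$region == "A&B"], 2)
  expect_equal(sum(same$count), 2)

  expect_error(venn_counts(list(A = "a")), "at least 2")
})

test_that("random venn instances match exhaustive membership enumeration", {
  set.seed(17)
  for (trial in 1:100) {
    k <- sample(2:4, 1)
    universe <- paste0("e", 1:12)
    sets <- lapply(seq_len(k), function(i) {
      sample(universe, sample(0:8, 1))
    })
    names(sets) <- LETTERS[seq_len(k)]
    vc <- venn_counts(sets)
    expect_equal(nrow(vc), 2^k - 1)
    # oracle: classify each union element by its exact membership pattern
    union <- unique(unlist(sets))
    oracle <- table(vapply(union, function(e) {
      paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    for (i in seq_len(nrow(vc))) {
      expected <- if (vc$region[i] %in% names(oracle)) {
        as.integer(oracle[[vc$region[i]]])
      } else 0L
      expect_equal(vc$count[i], expected)
    }
    expect_equal(sum(vc$count), length(union))
  }
})

test_that("summary report reconciles with the filter report and flags empty patients", {
  out <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(n_groups = 2, cells_per_group = 8,
                                      signature_size = 30,
                                      n_background_genes = 80,
                                      patients_per_group = 2, seed = 6), out)
  m <- ingest_variants(fx$dir, fx$metadata)
  # force one patient's cells out: P1 cells get too few genes to survive
  keep <- m$obs$sample_id != "P01"
  counts <- as.matrix(m$counts)
  counts[!keep, ] <- 0L
  counts[!keep, 1:3] <- 1L
  m_mod <- mutation_matrix(counts, obs = m$obs)
  cfg <- pipeline_config(min_genes_per_cell = 10, n_hvg = 50)
  qc <- qc_preprocess(m_mod, cfg)
  sr <- summary_report(qc, m_mod)
  expect_equal(sr$note[sr$patient == "P01"], "no cells passed filtering")
  expect_true(is.na(sr$mean_mutations_per_cell[sr$patient == "P01"]))
  expect_equal(sum(sr$n_filtered_cells), nrow(qc$matrix$counts))
  expect_equal(sum(sr$n_cells), nrow(m_mod$counts))

  # mean = brute-force mean of post-filter row sums per patient
  for (p in sr$patient[sr$note == ""]) {
    rows <- qc$matrix$obs$sample_id == p
    expect_equal(sr$mean_mutations_per_cell[sr$patient == p],
                 mean(Matrix::rowSums(qc$matrix$counts[rows, , drop = FALSE])))
  }

  paths <- write_summary_report(sr, file.path(out, "summary"))
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sr))
})

test_that("single-patient summary has one row", {
  counts <- matrix(rep(1:3, 40), 3, 40,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:40)))
  m <- mutation_matrix(counts, obs = tibble::tibble(sample_id = rep("P", 3)))
  qc <- qc_preprocess(m, pipeline_config(min_genes_per_cell = 5, n_hvg = 10))
  sr <- summary_report(qc, m)
  expect_equal(nrow(sr), 1)
  expect_equal(sr$n_mutated_genes, 40)
})
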