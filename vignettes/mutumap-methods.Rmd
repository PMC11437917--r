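---
title: "Methods: from per-cell somatic SNV tables to UMAP clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from per-cell somatic SNV tables to UMAP clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell whole-exome sequencing yields, after somatic variant calling and
annotation, one table of annotated single-nucleotide variants per cell. Each
row names the gene a variant falls in and its exonic consequence
(non-synonymous, synonymous, stopgain, ...). `mutumap` turns a directory (or
ZIP archive) of such ANNOVAR-style tables plus a per-patient metadata sheet
into a cells-by-genes *mutation-count* matrix, and then treats that matrix
the way single-cell expression workflows treat a count matrix: quality
filters, normalization, highly-variable-gene selection, PCA, a kNN graph, a
2-D UMAP embedding, and Leiden/Louvain community detection. The question the
output answers is whether cells group by a biological covariate — histological
subtype, tissue of origin — when described only by *which genes are mutated
and how often*.

# From variant rows to a count matrix

Each input file corresponds to one cell; the cell id is the file name minus
its recognized extension chain. Two ANNOVAR output dialects are detected
automatically: the `*_multianno.txt` table (header with `Gene.refGene` /
`ExonicFunc.refGene`-style columns) and the headerless
`exonic_variant_function` file (consequence in column 2, gene in column 3).
Counting rules, stated explicitly because annotator output leaves them open:

* duplicate rows describing the same variant (chrom, pos, ref, alt) within a
  cell are counted once;
* a row listing several genes (separated by `;` or `,`) increments **every**
  listed gene — total evidence is preserved, and the behaviour is visible in
  the API so users can pre-filter if they disagree;
* a variant annotated to multiple transcripts of one gene counts once for
  that gene;
* only single-nucleotide substitutions of the requested consequence classes
  are kept. The default keeps non-synonymous SNVs only; `keep_classes =
  functional_classes()` keeps everything, the mode intended for small
  cohorts where too few genes would otherwise survive filtering.

Entry `[c, g]` of the matrix is therefore the number of retained variant
records of cell `c` annotated to gene `g`; the gene universe is the union
over cells. Cells found in the input but absent from the metadata are kept
with their categorical fields set to the sentinel `"NA"` (a warning is
emitted; `strict = TRUE` turns this into an error) — a converter should not
silently drop data. The matrix is serialized in the AnnData on-disk HDF5
convention (`X` as compressed sparse rows, `obs`, `var`, optional `obsm`)
and is readable by the Python `anndata` package; a plain-TSV export is
written alongside for language-neutral inspection.

# The five-step preprocessing chain

The filters run once each, in this order, with these defaults:

| step | rule | default |
|------|------|---------|
| 1 | drop genes mutated in fewer than `min_cells_per_gene` cells | 3 |
| 2 | drop cells with fewer than `min_genes_per_cell` mutated genes | 30 |
| 3 | drop cells whose mutated-gene count strictly exceeds the `upper_percentile`-th percentile of retained cells | 98 |
| 4 | scale each cell to `target_sum`, then `log1p` | median of per-cell totals |
| 5 | keep the top `n_hvg` genes by binned normalized dispersion, then regress out per-cell totals | 3000 |

Decisions worth spelling out:

* **Single pass.** A gene may fall below the 3-cell support after cells are
  removed in steps 2–3; we accept that rather than iterating, matching the
  common single-pass convention of the workflow this chain adapts.
* **Boundaries.** "Fewer than 30" excludes 30 itself, so a cell with exactly
  30 mutated genes is kept. The percentile cut removes cells *strictly
  above* the threshold, so `upper_percentile = 100` removes nothing.
* **Percentile definition.** Linear interpolation (R's `quantile` type 7,
  identical to numpy's default) over the per-cell mutated-gene counts of the
  cells retained at that point. By default the 98th percentile is computed
  after the minimum-genes filter; `percentile_before_min_genes = TRUE` swaps
  the order, since the adapted workflow does not pin it down.
* **Normalization target.** The median of pre-normalization per-cell totals,
  so the typical cell is almost unchanged; any positive constant can be
  given instead. After scaling, every per-cell total equals the target to
  within floating-point error (the test suite enforces 1e-9 relative).
* **HVG selection.** Means and dispersions (variance/mean) are computed on
  the `expm1` scale of the log-normalized values (the Seurat-flavour
  convention); genes are assigned to 20 *equal-count* mean bins and the
  dispersion is z-scored within each bin. Equal-count bins keep every bin
  populated regardless of how skewed the mean distribution is, which makes
  the z-score well defined; bins holding a single gene, or with zero spread,
  get a normalized dispersion of 0. Ties are broken by stable input gene
  order. With very few genes the per-bin counts get too small for a
  meaningful z-score, so `n_bins` is exposed.
* **Regress-out.** Per gene, an ordinary least-squares fit on (intercept,
  per-cell total counts) is replaced by its residuals; the covariate is the
  *pre-normalization* total of the post-filter matrix. Residuals are exactly
  orthogonal to the covariate up to floating-point error. A constant
  covariate makes the slope undefined, so the step is skipped with a
  warning.
* **No variance scaling before PCA** unless `scale_before_pca = TRUE`: the
  published chain lists no scaling step, so the common extra step is opt-in
  rather than silently applied.

# Embedding and clustering

PCA uses an exact SVD for small matrices and a truncated SVD (irlba)
otherwise, with `n_pcs` capped below the matrix rank; component signs are
fixed so the largest-magnitude score is positive, which makes the scores
reproducible and independent of cell order. The `n_neighbors` nearest
neighbours in PC space (exact kd-tree search) are converted to a symmetric
fuzzy-simplicial connectivity graph: per cell, distances are offset by the
distance to the nearest neighbour and a bandwidth is calibrated by bisection
so the effective neighbourhood size is log2(k); the two directed graphs are
combined with the probabilistic t-conorm. Both the UMAP layout and the
community detection consume this same graph/kNN structure, so the picture
and the labels describe one topology.

The UMAP layout runs single-threaded from the precomputed neighbour list
with a fixed seed, making repeated runs bit-identical; below 10 cells the
spectral initialization is replaced by seeded random placement because the
truncated eigendecomposition needs more points than that. Leiden (modularity
objective) and Louvain run on the weighted graph at `resolution` (default
1.0); labels are renumbered `0..K-1` by descending cluster size so naming is
stable across runs. Defaults `n_pcs = 50`, `n_neighbors = 15`,
`resolution = 1`, `seed = 0` are the adapted workflow's conventional values;
all are exposed, and cluster counts on real data are sensitive to
`n_neighbors` and `resolution`, so they should be read as descriptive, not
canonical.

# Gene-set reports and Venn analytics

A gene *qualifies* for a patient when it is mutated in at least
`min_cells = 2` of that patient's cells, computed on the post-filter,
pre-HVG count matrix (the qualifying-gene rule is a reporting rule tied to
the QC'd data, not to the embedding subspace; a flag applies it to the raw
matrix instead). A group's set (per histology, tissue, ...) is the union of
its member patients' qualifying sets. For 2–4 groups the package counts the
2^k − 1 *exclusive* Venn regions — each union element contributes to exactly
one region, and region counts sum to the union size — and renders circles
(2–3 sets) or the classic 4-ellipse layout, placing each count at the
centroid of its region computed by grid rasterization rather than hardcoded
label positions. More than 4 groups is an error with advice to subset, not a
silent fallback.

The per-patient summary reports cells before filtering, cells surviving,
the mean per-cell retained variant count on the post-filter matrix, and the
qualifying-gene count; patients whose cells were all removed are flagged
`"no cells passed filtering"` with blank statistics rather than dropped.

# The synthetic-data generator

`generate_fixture()` emulates the group-separable structure the pipeline is
meant to detect: `n_groups` groups of cells, each with a disjoint signature
of `signature_size = 60` genes mutated in a member cell with probability
0.8, over a background in which any of the `n_background_genes = 400` extra
genes (and any signature gene of another group) is mutated with probability
0.02. Each group's cells are split across 2 patients; synonymous rows are
mixed in (30% of the non-synonymous row count) to exercise the consequence
filter; positions and alleles are synthetic and not tied to a genome build,
and gene symbols are `G0001...`, because the tests target counting,
filtering and clustering, not annotation fidelity. Everything is determined
by the seed.

What the fixture does *not* emulate — and what passing tests therefore do
not show about real data: allelic dropout and the extreme sparsity of
single-cell variant calling, mutational trinucleotide signatures, correlated
mutation burdens between related clones, and patients with widely different
cell counts. The fixture demonstrates that the machinery recovers planted
structure; it says nothing about whether real histological subtypes separate.

# Numerical and testing choices

Problem sizes in the test suite and the acceptance script are kept small —
tens of cells, hundreds of genes, 20 replicate datasets for the counting
check — because every property asserted (exact recount equality,
filter-boundary behaviour, orthogonality of residuals, ARI of planted
recovery) is scale-free. The planted-recovery check uses the generator's
default conditions (3 groups × 20 cells, signature 60, rates 0.8/0.02,
seed 0) and requires adjusted Rand index ≥ 0.9 against the planted labels.
Known limitations: input-order invariance is guaranteed for PC scores, the
graph and the cluster partition (labels are size-ordered), but the UMAP
layout is only seed-stable for a fixed input order, since the stochastic
layout consumes edges in storage order; and the ZIP writer emits stored
(uncompressed) archives with fixed timestamps so archives are deterministic.
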