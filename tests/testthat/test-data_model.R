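test_that("construction validates shapes and invariants", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "screen_dataset")
  expect_equal(dim(ds$counts), c(3L, 4L))
  expect_error(screen_dataset(matrix(-1, 1, 1), "g", "c",
                              data.frame(cell_id = "c", grna_id = "x"),
                              data.frame(grna_id = "x", target = "t",
                                         targeting = TRUE,
                                         grna_group = "x")),
               "negative")
  # assignment referencing unknown cell
  expect_error(screen_dataset(matrix(1, 1, 1), "g", "c1",
                              data.frame(cell_id = "c9", grna_id = "x"),
                              data.frame(grna_id = "x", target = "t",
                                         targeting = TRUE,
                                         grna_group = "x")),
               "dimension")
})

test_that("write/read round-trip preserves all fields (mtx and dense)", {
  ds <- random_dataset(n_genes = 12, n_cells = 40, seed = 5)
  for (dense in c(FALSE, TRUE)) {
    dir <- file.path(tempdir(), paste0("rt_", dense))
    write_dataset(ds, dir, dense = dense)
    ds2 <- read_dataset(
      file.path(dir, if (dense) "counts.tsv" else "counts.mtx"),
      file.path(dir, "grna_assignment.tsv"),
      file.path(dir, "grna_table.tsv"))
    expect_equal(as.matrix(ds2$counts), as.matrix(ds$counts),
                 ignore_attr = TRUE)
    expect_equal(ds2$response_ids, ds$response_ids)
    expect_equal(ds2$cell_ids, ds$cell_ids)
    expect_equal(ds2$grna_assignment$grna_id, ds$grna_assignment$grna_id)
    expect_equal(ds2$grna_table$targeting, ds$grna_table$targeting)
  }
})

test_that("QC matches a brute-force oracle and is idempotent", {
  ds <- random_dataset(n_genes = 200, n_cells = 400, seed = 11)
  # add a doublet cell and an unassigned cell by editing the assignment
  asn <- ds$grna_assignment
  asn <- rbind(asn, data.frame(cell_id = asn$cell_id[1],
                               grna_id = "nt2"))
  asn <- asn[asn$cell_id != ds$cell_ids[2], ]
  ds$grna_assignment <- asn
  thr <- qc_thresholds(min_gene_frac = 0.05, min_cells_per_grna = 30)
  q1 <- apply_dataset_qc(ds, thr)

  # oracle: explicit loops over the definition, same filter order
  tab <- table(asn$cell_id)
  keep_cells <- intersect(ds$cell_ids, names(tab)[tab == 1])
  cm <- as.matrix(ds$counts)[, keep_cells, drop = FALSE]
  keep_genes <- rownames(cm)[vapply(seq_len(nrow(cm)), function(g)
    mean(cm[g, ] > 0) >= thr$min_gene_frac, TRUE)]
  a2 <- asn[asn$cell_id %in% keep_cells, ]
  sz <- table(a2$grna_id)
  keep_grnas <- names(sz)[sz >= thr$min_cells_per_grna]
  keep_cells2 <- intersect(keep_cells,
                           a2$cell_id[a2$grna_id %in% keep_grnas])

  expect_setequal(q1$response_ids, keep_genes)
  expect_setequal(q1$cell_ids, keep_cells2)
  expect_setequal(q1$grna_table$grna_id, keep_grnas)
  # doublet cell must be gone
  expect_false(asn$cell_id[1] %in% q1$cell_ids)

  # idempotence and monotone dimensions
  q2 <- apply_dataset_qc(q1, thr)
  expect_equal(dim(q2$counts), dim(q1$counts))
  expect_equal(q2$cell_ids, q1$cell_ids)
  expect_true(all(dim(q1$counts) <= dim(ds$counts)))
})

test_that("default thresholds are 0.005 gene fraction and 10 cells", {
  thr <- qc_thresholds()
  expect_equal(thr$min_gene_frac, 0.005)
  expect_equal(thr$min_cells_per_grna, 10)
  expect_true(thr$require_single_grna)
})

test_that("covariate matrix: intercept, reference coding, rank checks", {
  ds <- random_dataset(n_genes = 10, n_cells = 60, seed = 2)
  Z0 <- build_covariate_matrix(ds, formula = character(0))
  expect_equal(dim(Z0), c(60L, 1L))
  expect_true(all(Z0 == 1))

  ds$covariates <- data.frame(
    batch = rep(c("a", "b", "c"), each = 20),
    depth = rexp(60) + 1)
  Z <- build_covariate_matrix(ds, c("batch", "depth"))
  expect_equal(ncol(Z), 4L)  # intercept + 2 indicators + 1 numeric
  expect_equal(qr(Z)$rank, ncol(Z))
  # numeric covariates are log-transformed
  expect_equal(Z[, "depth"], log(ds$covariates$depth),
               ignore_attr = TRUE)
  ds$covariates$flat <- rep(1.5, 60)
  expect_error(build_covariate_matrix(ds, "flat"), "collinearity")
})
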