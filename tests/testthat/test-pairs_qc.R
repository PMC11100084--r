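test_that("control-group set arithmetic on a fixed NT layout", {
  # 3 NT gRNAs with cell counts 5, 7, 9 plus a 19-cell targeting group
  n <- 40
  counts <- matrix(rpois(2 * n, 2), 2, n)
  grna <- c(rep("ntA", 5), rep("ntB", 7), rep("ntC", 9), rep("tg", 19))
  ds <- screen_dataset(
    counts, c("g1", "g2"), sprintf("c%02d", 1:n),
    data.frame(cell_id = sprintf("c%02d", 1:n), grna_id = grna),
    data.frame(grna_id = c("ntA", "ntB", "ntC", "tg"),
               target = c(rep("non-targeting", 3), "g1"),
               targeting = c(FALSE, FALSE, FALSE, TRUE),
               grna_group = c("ntA", "ntB", "ntC", "tg")))
  nc <- make_pair_specs("ntA", "g1", "negative_control", "nt_cells")
  rc <- resolve_cells(ds, nc)
  expect_length(rc$treatment, 5)
  expect_length(rc$control, 16)
  comp <- make_pair_specs("ntA", "g1", "negative_control", "complement")
  expect_length(resolve_cells(ds, comp)$control, 35)
  # discovery pair universe = targeting cells + NT cells (brute force)
  dp <- make_pair_specs("tg", "g2", "discovery", "nt_cells")
  rcd <- resolve_cells(ds, dp)
  oracle_universe <- sort(c(which(grna == "tg"),
                            which(grna %in% c("ntA", "ntB", "ntC"))))
  expect_equal(rcd$universe, oracle_universe)
  expect_equal(length(intersect(rcd$treatment, rcd$control)), 0)
})

test_that("effective sample size equals the brute-force double loop", {
  ds <- random_dataset(n_genes = 15, n_cells = 200, seed = 31)
  cm <- as.matrix(ds$counts)
  asn <- ds$grna_assignment
  for (g in c("nt1", "nt3", "tg2")) {
    for (r in sample(ds$response_ids, 4)) {
      spec <- make_pair_specs(g, r)
      oracle <- 0
      for (ci in seq_along(ds$cell_ids)) {
        has <- any(asn$grna_id[asn$cell_id == ds$cell_ids[ci]] == g)
        if (has && cm[r, ci] > 0) oracle <- oracle + 1
      }
      ess <- effective_sample_size(ds, spec)
      expect_equal(ess, oracle)
      expect_lte(ess, min(length(screenperm:::group_cells(ds, g)),
                          sum(cm[r, ] > 0)))
    }
  }
})

test_that("pairwise QC default is 7 and removal reasons partition", {
  ds <- random_dataset(n_genes = 30, n_cells = 250, seed = 12)
  pairs <- make_pair_specs(
    grna_group = rep(ds$grna_table$grna_group, 5),
    response_id = rep(sample(ds$response_ids, 5),
                      each = nrow(ds$grna_table)))
  qc <- pairwise_qc(pairs, ds)
  expect_true(all(qc$kept$ess >= 7))
  expect_equal(nrow(qc$kept) + nrow(qc$removed), nrow(pairs))
  if (nrow(qc$removed) > 0)
    expect_true(all(nchar(qc$removed$reason) > 0))
  qc0 <- pairwise_qc(pairs, ds, ess_min = 0)
  expect_equal(nrow(qc0$kept), nrow(pairs))
})

test_that("negative-control pair construction matches counting oracle", {
  ds <- random_dataset(n_genes = 100, n_cells = 400, n_nt = 5, n_tg = 3,
                       seed = 77)
  discovery <- make_pair_specs(
    grna_group = rep(paste0("tg", 1:3), each = 100),
    response_id = rep(ds$response_ids, 3))
  nc <- build_negative_control_pairs(ds, discovery, ess_min = 0, seed = 2)
  # candidates = d * n_genes = 500; matched down to 300
  expect_equal(nrow(nc), nrow(discovery))
  expect_true(all(!nc$grna_group %in%
                    ds$grna_table$grna_group[ds$grna_table$targeting]))
  # determinism
  nc2 <- build_negative_control_pairs(ds, discovery, ess_min = 0, seed = 2)
  expect_identical(nc$grna_group, nc2$grna_group)
  expect_identical(nc$response_id, nc2$response_id)
  # without matching pressure, candidate count is d * n_genes
  big_discovery <- make_pair_specs(rep("tg1", 600),
                                   rep(ds$response_ids, 6))
  expect_warning(
    nc_all <- build_negative_control_pairs(ds, big_discovery,
                                           ess_min = 0, seed = 2),
    "candidates")
  expect_equal(nrow(nc_all), 5 * 100)
})

test_that("single NT gRNA errors in NT-cells mode", {
  ds <- random_dataset(n_nt = 1, n_tg = 2, n_genes = 10, n_cells = 100,
                       seed = 3)
  expect_error(build_negative_control_pairs(
    ds, make_pair_specs("tg1", "g001")), "at least 2 NT")
})

test_that("positive-control pairs come from target-label joins", {
  ds <- random_dataset(n_genes = 20, n_cells = 150, n_nt = 4, n_tg = 3,
                       seed = 8)
  pc <- build_positive_control_pairs(ds)
  # join oracle over the metadata table
  gt <- ds$grna_table[ds$grna_table$targeting, ]
  oracle <- sum(toupper(gt$target) %in% toupper(ds$response_ids))
  expect_equal(nrow(pc), oracle)
  expect_true(all(pc$pair_type == "positive_control"))
  # NT groups never yield positive controls
  expect_false(any(pc$grna_group %in%
                     ds$grna_table$grna_group[!ds$grna_table$targeting]))
})
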