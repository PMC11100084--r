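test_that("prefix property: smaller samples are prefixes of larger", {
  bank <- resample_bank(50, seed = 9, "prefix")
  for (b in 1:10) {
    s3 <- permute_indicators(bank, 3, b)
    s10 <- permute_indicators(bank, 10, b)
    expect_true(all(s3 %in% s10))
    expect_length(s3, 3)
  }
  # complement of t = n-1 is a single index
  expect_length(setdiff(1:50, permute_indicators(bank, 49, 1)), 1)
  expect_error(permute_indicators(bank, 50, 1), "degenerate")
})

test_that("resamples are uniform over subsets (n=6, t=2 enumeration)", {
  bank <- resample_bank(6, seed = 123, "unif")
  B <- 60000
  o <- screenperm:::bank_orderings(bank, B)
  key <- apply(o[1:2, , drop = FALSE], 2, function(s)
    paste(sort(s), collapse = "-"))
  counts <- table(key)
  expect_length(counts, 15)
  p0 <- 1 / 15
  se <- sqrt(p0 * (1 - p0) / B)
  expect_true(all(abs(counts / B - p0) < 3.5 * se))
})

test_that("banks are reproducible functions of (seed, universe, index)", {
  b1 <- resample_bank(30, seed = 4, "k1")
  b2 <- resample_bank(30, seed = 4, "k1")
  expect_identical(permute_indicators(b1, 7, 5),
                   permute_indicators(b2, 7, 5))
  b3 <- resample_bank(30, seed = 4, "k2")
  expect_false(identical(permute_indicators(b1, 7, 5),
                         permute_indicators(b3, 7, 5)))
})

test_that("empirical p matches the naive double-loop oracle", {
  set.seed(5)
  for (k in 1:20) {
    z_null <- rnorm(sample(50:200, 1))
    z_obs <- rnorm(1)
    B <- length(z_null)
    right <- (1 + sum(vapply(z_null, function(z) z >= z_obs, TRUE))) /
      (B + 1)
    left <- (1 + sum(vapply(z_null, function(z) z <= z_obs, TRUE))) /
      (B + 1)
    expect_equal(empirical_p(z_obs, z_null, "right"), right)
    expect_equal(empirical_p(z_obs, z_null, "left"), left)
    expect_equal(empirical_p(z_obs, z_null, "two"),
                 min(1, 2 * min(left, right)))
  }
})

test_that("empirical p boundary conventions", {
  z_null <- rnorm(99)
  expect_equal(empirical_p(max(z_null) + 1, z_null, "right"), 0.01)
  expect_equal(empirical_p(0, rep(0, 99), "right"), 1)
  expect_gte(empirical_p(3, rnorm(99), "two"), 1 / 100)
})

test_that("two-sided p is monotone nonincreasing in |z_obs|", {
  set.seed(11)
  z_null <- rnorm(500)
  ps <- vapply(seq(0, 4, 0.25), function(z)
    empirical_p(z, z_null, "two"), 0.0)
  expect_true(all(diff(ps) <= 0))
})

test_that("test_pair: central z gives p near 1; adaptive promotion rule", {
  set.seed(13)
  n <- 300
  Z <- matrix(1, n, 1)
  Y <- rnbinom(n, size = 5, mu = 2)
  cfg <- adaptive_config(B1 = 200, B2 = 400, p_thresh = 0.01)
  tr <- sort(sample(n, 40))
  res <- test_pair(Y, Z, tr, setdiff(1:n, tr), cfg = cfg, seed = 2)
  expect_true(res$qc_pass)
  expect_true(res$p_two > 2 * cfg$p_thresh)  # null pair: almost surely
  expect_identical(res$stage, 1L)            # ... and never promoted
  expect_true(res$p_two >= res$p_left + res$p_right - 1 - 1e-12)
  expect_lte(min(res$p_left, res$p_right), res$p_two)
  expect_lte(res$p_two, 2 * min(res$p_left, res$p_right))

  # a strong signal pair must be promoted to stage 2
  Y2 <- Y
  Y2[tr] <- Y2[tr] + rpois(40, 6)
  res2 <- test_pair(Y2, Z, tr, setdiff(1:n, tr), cfg = cfg, seed = 2)
  expect_identical(res2$stage, 2L)
  expect_lt(res2$p_two, 0.05)
  expect_gt(res2$lfc, 0.5)
})

test_that("degenerate pairs are flagged, not fatal", {
  n <- 50
  res <- test_pair(rep(0L, n), matrix(1, n, 1), 1:10, 11:n,
                   cfg = adaptive_config(B1 = 100, B2 = 100))
  expect_false(res$qc_pass)
  expect_equal(res$p_two, 1)
  expect_match(res$error, "degenerate")
})

test_that("run_batch is deterministic across order and workers", {
  ds <- apply_dataset_qc(
    simulate_null_screen(synthetic_config(n_genes = 30, n_nt_grnas = 5,
                                          n_cells = 400, seed = 6)),
    qc_thresholds(min_gene_frac = 0.05, min_cells_per_grna = 10))
  genes <- head(ds$response_ids, 10)
  pairs <- make_pair_specs(
    grna_group = rep(unique(ds$grna_table$grna_group)[1:3], each = 10),
    response_id = rep(genes, 3), pair_type = "negative_control")
  cfg <- adaptive_config(B1 = 150, B2 = 300, p_thresh = 0.05)
  r1 <- run_batch(ds, pairs, cfg = cfg, seed = 5)
  r2 <- run_batch(ds, pairs[sample(nrow(pairs)), ], cfg = cfg, seed = 5)
  m <- match(r1$pair_id, r2$pair_id)
  expect_equal(r1$p_two, r2$p_two[m])
  expect_equal(r1$z_obs, r2$z_obs[m])
  r4 <- run_batch(ds, pairs, cfg = cfg, seed = 5, workers = 2)
  expect_equal(r1$p_two, r4$p_two)
  # single-pair batch equals test_pair through the same universe/bank
  one <- run_batch(ds, pairs[1, ], cfg = cfg, seed = 5)
  expect_equal(one$p_two, r1$p_two[r1$pair_id == one$pair_id])
})
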