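# Shared fixtures, all built in code.

# Tiny deterministic 3-gene x 4-cell dataset with hand-checkable values.
tiny_dataset <- function() {
  counts <- matrix(c(1, 0, 2, 0,
                     0, 3, 0, 1,
                     5, 1, 0, 2), nrow = 3, byrow = TRUE)
  screen_dataset(
    counts,
    response_ids = c("gA", "gB", "gC"),
    cell_ids = paste0("c", 1:4),
    grna_assignment = data.frame(cell_id = paste0("c", 1:4),
                                 grna_id = c("nt1", "nt2", "tg1", "nt1")),
    grna_table = data.frame(
      grna_id = c("nt1", "nt2", "tg1"),
      target = c("non-targeting", "non-targeting", "gA"),
      targeting = c(FALSE, FALSE, TRUE),
      grna_group = c("nt1", "nt2", "tg1")))
}

# Random medium fixture for oracle comparisons.
random_dataset <- function(n_genes = 40, n_cells = 300, n_nt = 6,
                           n_tg = 4, seed = 42) {
  set.seed(seed)
  means <- rgamma(n_genes, 0.5, rate = 2)
  sizes <- runif(n_genes, 1, 25)
  counts <- t(vapply(seq_len(n_genes), function(g)
    rnbinom(n_cells, size = sizes[g], mu = means[g]), numeric(n_cells)))
  grna_ids <- c(paste0("nt", seq_len(n_nt)), paste0("tg", seq_len(n_tg)))
  screen_dataset(
    counts,
    response_ids = sprintf("g%03d", seq_len(n_genes)),
    cell_ids = sprintf("c%04d", seq_len(n_cells)),
    grna_assignment = data.frame(
      cell_id = sprintf("c%04d", seq_len(n_cells)),
      grna_id = sample(grna_ids, n_cells, replace = TRUE)),
    grna_table = data.frame(
      grna_id = grna_ids,
      target = c(rep("non-targeting", n_nt),
                 sprintf("g%03d", seq_len(n_tg))),
      targeting = rep(c(FALSE, TRUE), c(n_nt, n_tg)),
      grna_group = grna_ids))
}

# Simulated (Y, Z, fit) triple for score-engine tests.
random_fit <- function(n = 200, q = 3, theta = 4, seed = 1,
                       family = "nb") {
  set.seed(seed)
  Z <- cbind(1, matrix(rnorm(n * (q - 1)), n))
  beta <- c(0.5, rnorm(q - 1, sd = 0.3))
  mu <- exp(as.vector(Z %*% beta))
  Y <- rnbinom(n, size = theta, mu = mu)
  if (all(Y == 0)) Y[1] <- 1
  list(Y = Y, Z = Z, fit = fit_null_glm(Y, Z, family = family))
}
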