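#' Configuration for synthetic screen generators
#'
#' Defaults state the generative model of the signal-free benchmark
#' screen: gene-wise NB means drawn i.i.d. from Gamma(shape 0.5, rate 2)
#' (mean 0.25 UMI per cell, typical of lowly expressed single-cell
#' genes) and gene-wise NB sizes from Uniform(1, 25); 5000 genes, 25
#' non-targeting gRNAs, and 10,000 cells, each cell receiving one gRNA
#' uniformly at random so expected cells per gRNA are equal.
#'
#' @param n_genes,n_nt_grnas,n_pc_grnas,n_cells dimensions.
#' @param gene_mean_shape,gene_mean_rate Gamma law of gene means.
#' @param size_low,size_high Uniform law of NB sizes.
#' @param seed integer seed (generators are pure functions of
#'   config + seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 5000, n_nt_grnas = 25,
                             n_pc_grnas = 0, n_cells = 10000,
                             gene_mean_shape = 0.5, gene_mean_rate = 2,
                             size_low = 1, size_high = 25, seed = 1) {
  stopifnot(n_genes > 0, n_nt_grnas > 0, n_cells > 0,
            gene_mean_shape > 0, gene_mean_rate > 0, size_low < size_high)
  structure(as.list(environment()), class = "synthetic_config")
}

# Build a sparse counts matrix gene-by-cell with per-gene NB laws.
# mean_mat_override: optional function(g) returning the length-n mean
# vector for gene g (used by the positive-control generator).
sample_nb_counts <- function(n_genes, n_cells, gene_means, gene_sizes,
                             mean_fn = NULL) {
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    mu <- if (is.null(mean_fn)) rep(gene_means[g], n_cells) else mean_fn(g)
    y <- rnbinom(n_cells, size = gene_sizes[g], mu = mu)
    nz <- which(y > 0)
    rows[[g]] <- list(j = nz, x = y[nz])
  }
  i <- rep.int(seq_len(n_genes), vapply(rows, function(r) length(r$j), 0L))
  Matrix::sparseMatrix(i = i,
                       j = unlist(lapply(rows, `[[`, "j")),
                       x = unlist(lapply(rows, `[[`, "x")),
                       dims = c(n_genes, n_cells))
}

#' Simulate the signal-free null screen
#'
#' All gRNAs are non-targeting; no gRNA affects any gene and no
#' technical factor affects either expression or assignment, so every
#' gRNA-gene pair is truly null. Counts are NB with gene-specific mean
#' and size drawn from the config's laws; each cell gets one gRNA
#' uniformly at random (multinomial assignment, equal expected cells
#' per gRNA).
#'
#' @param cfg a [synthetic_config()].
#' @return a [screen_dataset()] (covariates: computed library size).
#' @export
simulate_null_screen <- function(cfg = synthetic_config()) {
  set.seed(derive_seed(cfg$seed, "null_screen"))
  gene_means <- rgamma(cfg$n_genes, shape = cfg$gene_mean_shape,
                       rate = cfg$gene_mean_rate)
  gene_sizes <- runif(cfg$n_genes, cfg$size_low, cfg$size_high)
  counts <- sample_nb_counts(cfg$n_genes, cfg$n_cells, gene_means,
                             gene_sizes)
  response_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell_%05d", seq_len(cfg$n_cells))
  grna_ids <- sprintf("nt_grna_%02d", seq_len(cfg$n_nt_grnas))
  asn <- data.frame(cell_id = cell_ids,
                    grna_id = sample(grna_ids, cfg$n_cells, replace = TRUE))
  gt <- data.frame(grna_id = grna_ids, target = "non-targeting",
                   targeting = FALSE, grna_group = grna_ids)
  screen_dataset(counts, response_ids, cell_ids, asn, gt)
}

#' Simulate the positive-control screen
#'
#' A screen with known ground truth: each positive-control gRNA is
#' linked to one distinct gene (by default gRNA k to gene k), and for a
#' linked pair the gene's NB mean in that gRNA's cells is an independent
#' Gamma draw (while its control mean is a separate draw), so linked
#' pairs carry real signal of random magnitude. Unlinked pairs and all
#' NT pairs are null. Defaults: 125 genes, 25 positive-control gRNAs,
#' 100 NT gRNAs, 15,000 cells. No confounding.
#'
#' @param cfg a [synthetic_config()]; a standard call is
#'   `synthetic_config(n_genes = 125, n_nt_grnas = 100, n_pc_grnas = 25,
#'   n_cells = 15000)`.
#' @return list with `dataset` (a [screen_dataset()]) and `truth`
#'   (data.frame `grna_id`, `response_id`, `mean_control`,
#'   `mean_treatment`).
#' @export
simulate_positive_control_screen <- function(cfg = synthetic_config(
  n_genes = 125, n_nt_grnas = 100, n_pc_grnas = 25, n_cells = 15000)) {
  stopifnot(cfg$n_pc_grnas > 0, cfg$n_pc_grnas <= cfg$n_genes)
  set.seed(derive_seed(cfg$seed, "pc_screen"))
  n_grnas <- cfg$n_pc_grnas + cfg$n_nt_grnas
  grna_ids <- c(sprintf("pc_grna_%03d", seq_len(cfg$n_pc_grnas)),
                sprintf("nt_grna_%03d", seq_len(cfg$n_nt_grnas)))
  response_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell_%05d", seq_len(cfg$n_cells))
  cell_grna <- sample(n_grnas, cfg$n_cells, replace = TRUE)

  mean_control <- rgamma(cfg$n_genes, cfg$gene_mean_shape,
                         rate = cfg$gene_mean_rate)
  gene_sizes <- runif(cfg$n_genes, cfg$size_low, cfg$size_high)
  # bijective default linkage: PC gRNA k perturbs gene k
  mean_treatment <- rgamma(cfg$n_pc_grnas, cfg$gene_mean_shape,
                           rate = cfg$gene_mean_rate)
  mean_fn <- function(g) {
    mu <- rep(mean_control[g], cfg$n_cells)
    if (g <= cfg$n_pc_grnas) mu[cell_grna == g] <- mean_treatment[g]
    mu
  }
  counts <- sample_nb_counts(cfg$n_genes, cfg$n_cells, mean_control,
                             gene_sizes, mean_fn = mean_fn)
  asn <- data.frame(cell_id = cell_ids, grna_id = grna_ids[cell_grna])
  gt <- data.frame(
    grna_id = grna_ids,
    target = c(response_ids[seq_len(cfg$n_pc_grnas)],
               rep("non-targeting", cfg$n_nt_grnas)),
    targeting = c(rep(TRUE, cfg$n_pc_grnas), rep(FALSE, cfg$n_nt_grnas)),
    grna_group = grna_ids)
  truth <- data.frame(grna_id = grna_ids[seq_len(cfg$n_pc_grnas)],
                      response_id = response_ids[seq_len(cfg$n_pc_grnas)],
                      mean_control = mean_control[seq_len(cfg$n_pc_grnas)],
                      mean_treatment = mean_treatment)
  list(dataset = screen_dataset(counts, response_ids, cell_ids, asn, gt),
       truth = truth)
}

#' Configuration for the confounding/misspecification simulation study
#'
#' The study emulates a single gene-perturbation pair whose expression
#' depends on technical factors (a two-level batch shifting the log-mean
#' by +/- `batch_effect`, and a standard-normal continuous factor with
#' coefficient `cont_effect`), under four arms: {confounded,
#' unconfounded} x {size parameter handed to the methods = theta_star,
#' 5 theta_star}. In the confounded arms the perturbation indicator
#' depends on batch (assignment probabilities `pi_confounded`); in the
#' unconfounded arms it is i.i.d. Bernoulli(`pi_hat`).
#'
#' @param n_cells cells per dataset.
#' @param beta0 intercept of the log-mean (default `log(0.5)`).
#' @param batch_effect half-spread of the batch effect on the log scale.
#' @param cont_effect coefficient of the continuous factor.
#' @param theta_star true NB size parameter.
#' @param misspec_factor factor applied to theta_star in the
#'   misspecified arms (fixed design value 5).
#' @param pi_hat marginal treatment probability.
#' @param pi_confounded length-2 batch-wise treatment probabilities
#'   (mean equals `pi_hat` under equal batch sizes).
#' @param B_datasets number of replicate datasets.
#' @param seed integer seed.
#' @return list of class `camp_config`.
#' @export
camp_config <- function(n_cells = 2000, beta0 = log(0.5),
                        batch_effect = 0.75, cont_effect = 0.25,
                        theta_star = 4, misspec_factor = 5,
                        pi_hat = 0.05, pi_confounded = c(0.02, 0.08),
                        B_datasets = 500, seed = 1) {
  stopifnot(theta_star > 0, pi_hat > 0, pi_hat < 1,
            length(pi_confounded) == 2, B_datasets > 0)
  structure(as.list(environment()), class = "camp_config")
}

#' Simulate the confounding study bundle
#'
#' Draws one covariate matrix `Z` (intercept, batch indicator,
#' continuous factor), one confounded perturbation vector `X`
#' (batch-dependent Bernoulli), one unconfounded vector `X_tilde`
#' (i.i.d. Bernoulli(`pi_hat`)), and `B_datasets` independent response
#' vectors `Y_b ~ NB(exp(beta' Z_i), theta_star)`. The same responses
#' are paired with `[X, Z]` (confounded) and `[X_tilde, Z]`
#' (unconfounded); the theta arms differ only in the size parameter
#' handed to the methods.
#'
#' @param cfg a [camp_config()].
#' @return list with `Z`, `batch`, `X_conf`, `X_unconf`, `Y` (cells x
#'   B_datasets matrix), `beta_true`, and `cfg`.
#' @export
simulate_camp_study <- function(cfg = camp_config()) {
  set.seed(derive_seed(cfg$seed, "camp"))
  n <- cfg$n_cells
  batch <- rbinom(n, 1, 0.5)
  cont <- rnorm(n)
  Z <- cbind(intercept = 1, batch = batch, cont = cont)
  # batch contributes -batch_effect / +batch_effect to the log-mean
  beta_true <- c(cfg$beta0 - cfg$batch_effect, 2 * cfg$batch_effect,
                 cfg$cont_effect)
  mu <- as.vector(exp(Z %*% beta_true))
  X_conf <- rbinom(n, 1, cfg$pi_confounded[batch + 1])
  X_unconf <- rbinom(n, 1, cfg$pi_hat)
  Y <- vapply(seq_len(cfg$B_datasets), function(b)
    rnbinom(n, size = cfg$theta_star, mu = mu), numeric(n))
  list(Z = Z, batch = batch, X_conf = X_conf, X_unconf = X_unconf,
       Y = Y, beta_true = beta_true, cfg = cfg)
}

#' Evaluate three methods on the confounding study
#'
#' Per replicate dataset and arm, three tests of the (truly null)
#' perturbation effect are computed:
#' \describe{
#'   \item{permuted_score}{the package's test: permutation p-value of
#'     the NB score statistic, size parameter fixed at the arm's value,
#'     empirical (no skew-normal) to isolate the permutation property;}
#'   \item{nb_regression}{the parametric NB score test, comparing the
#'     same statistic to the standard Gaussian;}
#'   \item{perm_sum}{the plain permutation test whose statistic is the
#'     sum of expressions in treatment cells (no covariate
#'     adjustment).}
#' }
#' The permuted-score test is expected to hold its level in all four
#' arms (valid when either the perturbation is unconfounded or the NB
#' mean model is correct up to theta); `perm_sum` is expected to be
#' anticonservative under confounding, and `nb_regression` under
#' confounding combined with a misspecified theta.
#'
#' @param bundle from [simulate_camp_study()].
#' @param B_perm permutations per replicate for the permutation tests.
#' @param alphas nominal levels at which rejection rates are reported.
#' @return data.frame: `method`, `confounded`, `theta_used_factor`,
#'   `alpha`, `rejection_rate`, `n_reps`; attribute `"pvals"` holds the
#'   per-replicate p-value arrays.
#' @export
run_camp_evaluation <- function(bundle, B_perm = 500,
                                alphas = c(0.01, 0.05, 0.1)) {
  cfg <- bundle$cfg
  n <- cfg$n_cells
  Breps <- cfg$B_datasets
  thetas <- c(correct = cfg$theta_star,
              misspecified = cfg$misspec_factor * cfg$theta_star)
  arms <- expand.grid(confounded = c(TRUE, FALSE),
                      theta = names(thetas), stringsAsFactors = FALSE)
  bank <- resample_bank(n, derive_seed(cfg$seed, "camp_perms"), "camp")
  orderings <- bank_orderings(bank, B_perm)

  pvals <- list()
  for (k in seq_len(nrow(arms))) {
    conf <- arms$confounded[k]
    th <- thetas[[arms$theta[k]]]
    X <- if (conf) bundle$X_conf else bundle$X_unconf
    idx <- which(X == 1)
    t_ <- length(idx)
    p_score <- p_nb <- p_sum <- numeric(Breps)
    for (b in seq_len(Breps)) {
      Y <- bundle$Y[, b]
      fit <- fit_null_glm(Y, bundle$Z, family = th)
      pc <- precompute_score(fit, bundle$Z)
      z_obs <- score_stat(idx, pc)
      z_null <- score_stats_permuted(pc, orderings, t_)
      p_score[b] <- empirical_p(z_obs, z_null, "two")
      p_nb[b] <- 2 * pnorm(-abs(z_obs))
      s_obs <- sum(Y[idx])
      s_null <- sum_stats_prefix_cpp(Y, orderings, t_)
      p_sum[b] <- empirical_p(s_obs, s_null, "two")
    }
    key <- paste0(ifelse(conf, "confounded", "unconfounded"), ".",
                  arms$theta[k])
    pvals[[key]] <- list(permuted_score = p_score, nb_regression = p_nb,
                         perm_sum = p_sum)
  }

  rows <- list()
  for (key in names(pvals)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    for (m in names(pvals[[key]])) {
      for (a in alphas) {
        rows[[length(rows) + 1]] <- data.frame(
          method = m, confounded = parts[1] == "confounded",
          theta_used = parts[2], alpha = a,
          rejection_rate = mean(pvals[[key]][[m]] <= a),
          n_reps = Breps)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pvals") <- pvals
  out
}
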