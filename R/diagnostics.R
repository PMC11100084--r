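#' Relative expression transform
#'
#' `r = 1000 * ln(u/l + 1)` for UMI count `u` and library size `l > 0`;
#' a sparsity-robust display scale for single-gene expression.
#'
#' @param u nonnegative UMI count(s).
#' @param l positive library size(s).
#' @return numeric.
#' @export
relative_expression <- function(u, l) {
  if (any(l <= 0)) stop("input error: library size must be positive")
  if (any(u < 0)) stop("input error: negative UMI count")
  1000 * log(u / l + 1)
}

# Standardized Wilcoxon rank-sum statistic with mid-ranks and tie
# correction; returns z (Gaussian scale under H0).
wilcoxon_z <- function(y, treatment_idx) {
  n <- length(y)
  t_ <- length(treatment_idx)
  r <- rank(y)  # mid-ranks
  R <- sum(r[treatment_idx])
  mu <- t_ * (n + 1) / 2
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  v <- t_ * (n - t_) / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(NA_real_)
  (R - mu) / sqrt(v)
}

#' Exact versus asymptotic Wilcoxon comparison
#'
#' For one perturbation-gene pair: computes the (tie-corrected,
#' standardized) rank-sum statistic on library-size-normalized
#' expressions, the asymptotic two-sided p-value from the standard
#' Gaussian, and the exact p-value from `B` permutations of the
#' treatment labels (add-one convention). Also reports `p_ratio =
#' p_exact / p_asymptotic` and the KS distance of the standardized
#' permuted statistics from the standard Gaussian — the diagnostic for
#' how sparsity degrades the Gaussian approximation.
#'
#' @param y_norm library-size-normalized expression vector.
#' @param treatment_idx treatment cell indices.
#' @param B permutation count (the reference protocol uses 200,000;
#'   reduce for testing).
#' @param seed integer seed.
#' @return list of class `wilcoxon_comparison`: `p_asymptotic`,
#'   `p_exact`, `p_ratio`, `ks_gof`, `ess`, `degenerate`.
#' @export
wilcoxon_exact_vs_asymptotic <- function(y_norm, treatment_idx,
                                         B = 200000, seed = 1) {
  n <- length(y_norm)
  t_ <- length(treatment_idx)
  stopifnot(t_ > 0, t_ < n)
  ess <- sum(y_norm[treatment_idx] > 0)
  if (length(unique(y_norm)) == 1) {
    return(structure(list(p_asymptotic = 1, p_exact = 1, p_ratio = 1,
                          ks_gof = NA_real_, ess = ess, degenerate = TRUE),
                     class = "wilcoxon_comparison"))
  }
  z_obs <- wilcoxon_z(y_norm, treatment_idx)
  p_asym <- 2 * pnorm(-abs(z_obs))
  set.seed(derive_seed(seed, "wilcoxon", n, t_))
  z_null <- vapply(seq_len(B), function(b) {
    wilcoxon_z(y_norm, sample.int(n, t_))
  }, 0.0)
  p_exact <- min(1, 2 * min((1 + sum(z_null <= z_obs)) / (B + 1),
                            (1 + sum(z_null >= z_obs)) / (B + 1)))
  ks <- suppressWarnings(
    as.numeric(ks.test(z_null, "pnorm")$statistic))
  structure(list(p_asymptotic = p_asym, p_exact = p_exact,
                 p_ratio = p_exact / p_asym, ks_gof = ks, ess = ess,
                 degenerate = FALSE),
            class = "wilcoxon_comparison")
}

#' Fisher exact test of gRNA presence against a categorical factor
#'
#' Builds the 2 x k contingency table of a gRNA's presence/absence
#' across the levels of a technical factor (e.g. biological replicate)
#' and returns the Fisher exact p-value — the confounding diagnostic
#' for gRNA assignment. Falls back to a simulated p-value when the
#' exact network algorithm is infeasible for the table.
#'
#' @param ds a [screen_dataset()].
#' @param grna_id single gRNA id.
#' @param factor_name name of a categorical covariate column.
#' @return p-value in (0, 1].
#' @export
confounding_grna_test <- function(ds, grna_id, factor_name) {
  fac <- factor(ds$covariates[[factor_name]])
  if (nlevels(fac) < 2) stop("factor must have >= 2 levels")
  asn <- ds$grna_assignment
  present <- ds$cell_ids %in% asn$cell_id[asn$grna_id == grna_id]
  tab <- table(present, fac)
  if (nrow(tab) < 2 || any(colSums(tab) == 0)) return(1)
  res <- tryCatch(fisher.test(tab),
                  error = function(e)
                    fisher.test(tab, simulate.p.value = TRUE, B = 1e5))
  res$p.value
}

#' Likelihood-ratio test of a factor's effect on gene expression
#'
#' Fits two NB regressions of a gene's counts: one with library size
#' only, one with library size plus the factor's indicator columns
#' (theta re-estimated in each model), and compares them by a
#' chi-square likelihood-ratio test with df = number of added columns.
#' The confounding diagnostic for gene expression.
#'
#' @param ds a [screen_dataset()].
#' @param response_id gene to test.
#' @param factor_name categorical covariate name.
#' @return p-value, or `NA` with a warning if either fit fails.
#' @export
confounding_gene_test <- function(ds, response_id, factor_name) {
  Y <- as.numeric(ds$counts[response_id, ])
  Z0 <- build_covariate_matrix(ds, "library_size")
  Z1 <- build_covariate_matrix(ds, c("library_size", factor_name))
  f0 <- tryCatch(fit_null_glm(Y, Z0), error = function(e) NULL)
  f1 <- tryCatch(fit_null_glm(Y, Z1), error = function(e) NULL)
  if (is.null(f0) || is.null(f1) || !f0$converged || !f1$converged) {
    warning("NB fit failed or did not converge for ", response_id)
    return(NA_real_)
  }
  lr <- 2 * (f1$loglik - f0$loglik)
  df <- ncol(Z1) - ncol(Z0)
  pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}

#' Effective-sample-size bins
#'
#' Either explicit integer interval edges (default: the reference
#' stratification `[7,10], [11,16], [17,27], [28,46], [47,121]`) or
#' equal-frequency auto-binning of the observed ESS values into
#' `n_bins` strata.
#'
#' @param edges list of length-2 integer vectors (inclusive intervals),
#'   or `NULL` for auto-binning.
#' @param n_bins bins for auto mode.
#' @return object of class `ess_bins`.
#' @export
ess_bins <- function(edges = list(c(7, 10), c(11, 16), c(17, 27),
                                  c(28, 46), c(47, 121)),
                     n_bins = 5) {
  if (!is.null(edges)) {
    lo <- vapply(edges, `[`, 0, 1)
    hi <- vapply(edges, `[`, 0, 2)
    stopifnot(all(lo <= hi), all(diff(lo) > 0), all(hi[-length(hi)] < lo[-1]))
  }
  structure(list(edges = edges, n_bins = n_bins), class = "ess_bins")
}

#' ESS-stratified calibration summaries
#'
#' Bins pair results by effective sample size and, per bin, reports the
#' sorted p-values with their expected uniform quantiles `k/(m+1)`, a
#' pointwise 95% band from the Beta(k, m+1-k) order-statistic
#' distribution, and the KS distance from Uniform(0,1) — the inputs to
#' a stratified QQ plot.
#'
#' @param results data.frame with columns `p_two` and `ess` (e.g. from
#'   [run_batch()]).
#' @param bins an [ess_bins()].
#' @return list of per-bin data.frames (`p`, `expected`, `lower`,
#'   `upper`) with attributes `ks` and `label`; empty bins are skipped.
#' @export
stratified_calibration <- function(results, bins = ess_bins()) {
  if (!is.null(bins$edges)) {
    members <- lapply(bins$edges, function(e)
      which(results$ess >= e[1] & results$ess <= e[2]))
    labels <- vapply(bins$edges, function(e)
      sprintf("[%d,%d]", e[1], e[2]), "")
  } else {
    # equal-frequency strata by ESS rank (sizes within one of each other)
    ord <- order(results$ess)
    grp <- rep(seq_len(bins$n_bins),
               diff(round(seq(0, length(ord),
                              length.out = bins$n_bins + 1))))
    members <- split(ord, grp)
    labels <- vapply(members, function(ix)
      sprintf("[%d,%d]", min(results$ess[ix]), max(results$ess[ix])), "")
  }
  out <- list()
  for (k_bin in seq_along(members)) {
    ix <- members[[k_bin]]
    m <- length(ix)
    if (m == 0) next
    p <- sort(results$p_two[ix])
    k <- seq_len(m)
    df <- data.frame(p = p, expected = k / (m + 1),
                     lower = qbeta(0.025, k, m + 1 - k),
                     upper = qbeta(0.975, k, m + 1 - k))
    attr(df, "ks") <- max(abs(p - k / m), abs(p - (k - 1) / m))
    attr(df, "label") <- labels[k_bin]
    out[[labels[k_bin]]] <- df
  }
  out
}
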