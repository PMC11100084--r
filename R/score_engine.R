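#' Precompute spectral factors for fast score statistics
#'
#' For a binary treatment vector x with index set `idx`, the GLM score
#' statistic is
#' `z = sum(a[idx]) / sqrt(sum(w[idx]) - || S %*% colSums(D[idx,]) ||^2)`
#' where `a = w * working_resid` (equivalently
#' `(Y - mu)/(1 + mu/theta)`), `D` has rows `w_i * Z_i`, and
#' `S = Lambda^{-1/2} Q'` comes from the symmetric eigendecomposition
#' `Z'WZ = Q Lambda Q'`. `S` satisfies `S'S = (Z'WZ)^{-1}`, so the
#' denominator equals the quadratic form `x'Wx - x'WZ (Z'WZ)^{-1} Z'Wx`
#' while costing only `O(t q)` per treatment set of size t.
#'
#' @param fit a [fit_null_glm()] result.
#' @param Z the covariate matrix used in the fit.
#' @return object of class `score_precompute` with fields `a`, `w`, `D`,
#'   `S`, `n`, `q`.
#' @export
precompute_score <- function(fit, Z) {
  w <- fit$w
  n <- length(w)
  stopifnot(nrow(Z) == n)
  ZtWZ <- crossprod(Z, Z * w)
  eig <- eigen(ZtWZ, symmetric = TRUE)
  if (any(eig$values <= 0))
    stop("rank-deficiency error: Z'WZ has a non-positive eigenvalue")
  S <- diag(1 / sqrt(eig$values), nrow = length(eig$values)) %*% t(eig$vectors)
  recon <- tcrossprod(eig$vectors %*% diag(sqrt(eig$values),
                                           nrow = length(eig$values)))
  if (max(abs(recon - ZtWZ)) > 1e-8 * max(abs(ZtWZ)))
    stop("rank-deficiency error: eigendecomposition reconstruction failed")
  structure(list(a = w * fit$working_resid, w = w,
                 D = Z * w, S = S, n = n, q = ncol(Z)),
            class = "score_precompute")
}

#' Score statistic for one treatment index set (spectral fast path)
#'
#' @param x_idx sorted integer indices (1-based) of the treatment cells;
#'   must be a nonempty strict subset of the cells.
#' @param pc a [precompute_score()] object.
#' @return the scalar score z-statistic.
#' @export
score_stat <- function(x_idx, pc) {
  t_ <- length(x_idx)
  if (t_ == 0 || t_ >= pc$n)
    stop("degenerate-treatment error: treatment set empty or all cells")
  num <- sum(pc$a[x_idx])
  u <- colSums(pc$D[x_idx, , drop = FALSE])
  v2 <- sum(pc$w[x_idx]) - sum((pc$S %*% u)^2)
  if (v2 <= 0)
    stop("numerical-degeneracy error: nonpositive score variance (t=", t_, ")")
  num / sqrt(v2)
}

#' Dense reference evaluation of the score statistic
#'
#' Evaluates the score formula directly with an explicit `(Z'WZ)^{-1}`
#' solve. Used as a correctness oracle for the spectral path.
#'
#' @param x full binary 0/1 vector over cells.
#' @param fit a [fit_null_glm()] result.
#' @param Z covariate matrix.
#' @return the scalar score z-statistic.
#' @export
score_stat_dense <- function(x, fit, Z) {
  w <- fit$w
  num <- sum(x * w * fit$working_resid)
  ZtWZ <- crossprod(Z, Z * w)
  ZtWx <- crossprod(Z, w * x)
  v2 <- sum(x * w * x) - as.numeric(crossprod(ZtWx, solve(ZtWZ, ZtWx)))
  if (v2 <= 0) stop("numerical-degeneracy error: nonpositive score variance")
  num / sqrt(v2)
}

#' QR-decomposition reference evaluation of the score statistic
#'
#' The classical formulation: with `G = W^{1/2} Z` and its thin QR
#' factorization `G = QR`, the denominator quadratic form equals
#' `||xt||^2 - ||Q' xt||^2` for `xt = W^{1/2} x`. Reference/benchmark
#' path only.
#'
#' @inheritParams score_stat_dense
#' @return the scalar score z-statistic.
#' @export
score_stat_qr <- function(x, fit, Z) {
  w <- fit$w
  sw <- sqrt(w)
  qrG <- qr(Z * sw)
  xt <- sw * x
  proj <- qr.qty(qrG, xt)[seq_len(qrG$rank)]
  v2 <- sum(xt^2) - sum(proj^2)
  if (v2 <= 0) stop("numerical-degeneracy error: nonpositive score variance")
  sum(x * w * fit$working_resid) / sqrt(v2)
}

# Batch evaluation over permutation prefixes: orderings is an n x B
# integer matrix of permuted indices; returns the B score statistics for
# the treatment sets formed by the first t entries of each column.
score_stats_permuted <- function(pc, orderings, t_) {
  stopifnot(t_ > 0, t_ < pc$n)
  z <- score_stats_prefix_cpp(pc$a, pc$w, pc$D, pc$S, orderings, as.integer(t_))
  if (anyNA(z))
    stop("numerical-degeneracy error: nonpositive score variance in resample")
  z
}
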