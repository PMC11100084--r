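#' Shared without-replacement resample bank
#'
#' Holds B independent uniformly random orderings (permutations) of a
#' pair's cell universe `{1..n}`. Taking the first t entries of an
#' ordering yields a uniform without-replacement sample of size t, so a
#' single bank serves every treatment size — the inductive
#' without-replacement (IWOR) scheme that lets all pairs sharing a cell
#' universe reuse one set of resamples. Orderings are a pure function of
#' `(seed, universe_key, resample index)`: ordering b is drawn under a
#' seed derived from those three values, so banks are reproducible and
#' extensible (stage-2 resamples are fresh indices, not regenerated
#' stage-1 ones).
#'
#' @param n universe size.
#' @param seed global integer seed.
#' @param universe_key character key identifying the cell universe
#'   (pairs with identical universes share banks and hence resamples).
#' @return object of class `resample_bank` (an environment caching the
#'   realized orderings matrix).
#' @export
resample_bank <- function(n, seed, universe_key = "u") {
  e <- new.env(parent = emptyenv())
  e$n <- as.integer(n)
  e$seed <- as.integer(seed)
  e$universe_key <- universe_key
  e$orderings <- matrix(integer(0), nrow = n, ncol = 0)
  class(e) <- "resample_bank"
  e
}

# Ensure orderings for resample indices 1..B are realized; returns the
# n x B matrix (no copy when exactly B are realized).
bank_orderings <- function(bank, B) {
  have <- ncol(bank$orderings)
  if (B > have) {
    extra <- vapply((have + 1L):B, function(b) {
      rs <- derive_seed(bank$seed, bank$universe_key, b)
      set.seed(rs)
      sample.int(bank$n)
    }, integer(bank$n))
    bank$orderings <- cbind(bank$orderings, extra)
  }
  if (B == ncol(bank$orderings)) bank$orderings
  else bank$orderings[, seq_len(B), drop = FALSE]
}

# Contiguous slice of resample indices [from, to], cached in the bank so
# repeated stage accesses do not re-copy.
bank_range <- function(bank, from, to) {
  key <- paste0("r", from, "_", to)
  cached <- bank$range_cache[[key]]
  if (!is.null(cached)) return(cached)
  o <- bank_orderings(bank, to)
  sl <- if (from == 1L && to == ncol(o)) o
        else o[, from:to, drop = FALSE]
  if (is.null(bank$range_cache)) bank$range_cache <- list()
  bank$range_cache[[key]] <- sl
  sl
}

#' Without-replacement treatment sample from the bank
#'
#' @param bank a [resample_bank()].
#' @param t_ treatment size, `0 < t_ < n`.
#' @param b resample index (1-based).
#' @return sorted integer index set of size `t_`.
#' @export
permute_indicators <- function(bank, t_, b) {
  if (t_ <= 0 || t_ >= bank$n)
    stop("degenerate error: treatment size must satisfy 0 < t < n")
  o <- bank_orderings(bank, b)
  sort(o[seq_len(t_), b])
}

#' Adaptive permutation-testing configuration
#'
#' Two-stage scheme: compute an empirical p from `B1` resamples; pairs
#' whose stage-1 p exceeds `p_thresh` stop there, promising pairs are
#' re-tested with `B2` fresh resamples (stage-2 p uses only those).
#'
#' @param B1 stage-1 resample count (>= 100).
#' @param B2 stage-2 resample count (>= B1).
#' @param p_thresh promotion threshold in (0, 1).
#' @param side `"two"`, `"left"`, or `"right"`.
#' @return list of class `adaptive_config`.
#' @export
adaptive_config <- function(B1 = 500, B2 = 5000, p_thresh = 0.01,
                            side = "two") {
  stopifnot(B1 >= 100, B2 >= B1, p_thresh > 0, p_thresh < 1,
            side %in% c("two", "left", "right"))
  structure(list(B1 = as.integer(B1), B2 = as.integer(B2),
                 p_thresh = p_thresh, side = side),
            class = "adaptive_config")
}

#' Empirical permutation p-value
#'
#' Add-one convention: right-sided p is `(1 + #\{z_b >= z_obs\})/(B+1)`,
#' left-sided analogous, two-sided `min(1, 2 min(left, right))`. The
#' add-one rule guarantees validity (p >= 1/(B+1), never 0).
#'
#' @param z_obs observed statistic.
#' @param z_null vector of null statistics.
#' @param side `"two"`, `"left"`, or `"right"`.
#' @return probability in (0, 1].
#' @export
empirical_p <- function(z_obs, z_null, side = c("two", "left", "right")) {
  side <- match.arg(side)
  B <- length(z_null)
  stopifnot(B > 0)
  right <- (1 + sum(z_null >= z_obs)) / (B + 1)
  left <- (1 + sum(z_null <= z_obs)) / (B + 1)
  switch(side, right = right, left = left,
         two = min(1, 2 * min(left, right)))
}

# p-values on all three sides from either the skew-normal fit (when its
# goodness of fit passes) or the empirical null.
all_side_p <- function(z_obs, z_null, sn_fit) {
  if (!is.null(sn_fit) && sn_fit$ok) {
    list(left = tail_p(sn_fit, z_obs, "left"),
         right = tail_p(sn_fit, z_obs, "right"),
         two = tail_p(sn_fit, z_obs, "two"),
         method = "skew-normal")
  } else {
    list(left = empirical_p(z_obs, z_null, "left"),
         right = empirical_p(z_obs, z_null, "right"),
         two = empirical_p(z_obs, z_null, "two"),
         method = "empirical")
  }
}

# Log2 fold change of library-size-normalized mean expression, treatment
# over control, with a 0.5/n pseudocount on the normalized means.
compute_lfc <- function(Y, libsize, treatment_idx, control_idx) {
  norm_mean <- function(idx) {
    mean(Y[idx] / libsize[idx]) + 0.5 / mean(libsize)
  }
  log2(norm_mean(treatment_idx) / norm_mean(control_idx))
}

#' Test one perturbation-response pair
#'
#' The full per-pair procedure: fit the null NB GLM of the response on
#' the technical covariates over the pair's cell universe (treatment
#' plus control cells), compute the observed score statistic, then run
#' the adaptive permutation test, permuting the treatment label via the
#' shared resample bank. P-values come from a skew-normal fit to the
#' null statistics when its goodness of fit passes, otherwise from the
#' empirical permutation distribution. Degenerate pairs (e.g. all-zero
#' expression in the universe) are flagged, not fatal.
#'
#' @param Y response counts over the universe (treatment then control
#'   ordering does not matter; indices refer to this vector).
#' @param Z covariate matrix over the universe.
#' @param treatment_idx,control_idx disjoint 1-based index sets whose
#'   union is the universe `1..length(Y)`.
#' @param cfg an [adaptive_config()].
#' @param family passed to [fit_null_glm()].
#' @param seed global seed (per-pair streams derived internally).
#' @param bank optional pre-built [resample_bank()] over the universe;
#'   supply one to share resamples across pairs.
#' @param pair_id identifier stored in the result.
#' @param libsize optional library sizes for the fold-change estimate
#'   (defaults to `colSums` not being available here: `rep(1, n)`).
#' @return object of class `pair_result` with fields `pair_id`, `z_obs`,
#'   `n_treatment`, `p_left`, `p_right`, `p_two`, `p_method`, `stage`,
#'   `lfc`, `sn_fit`, `qc_pass`, `error`.
#' @export
test_pair <- function(Y, Z, treatment_idx, control_idx,
                      cfg = adaptive_config(), family = "nb", seed = 1,
                      bank = NULL, pair_id = "pair", libsize = NULL) {
  n <- length(Y)
  stopifnot(length(intersect(treatment_idx, control_idx)) == 0,
            length(treatment_idx) > 0, length(control_idx) > 0,
            setequal(c(treatment_idx, control_idx), seq_len(n)))
  if (is.null(libsize)) libsize <- rep(1, n)
  fail <- function(msg) {
    structure(list(pair_id = pair_id, z_obs = NA_real_,
                   n_treatment = length(treatment_idx),
                   p_left = 1, p_right = 1, p_two = 1,
                   p_method = "none", stage = 0L, lfc = NA_real_,
                   sn_fit = NULL, qc_pass = FALSE, error = msg),
              class = "pair_result")
  }
  fit <- tryCatch(fit_null_glm(Y, Z, family = family),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) return(fail(fit))
  pc <- tryCatch(precompute_score(fit, Z),
                 error = function(e) conditionMessage(e))
  if (is.character(pc)) return(fail(pc))
  t_ <- length(treatment_idx)
  z_obs <- tryCatch(score_stat(sort(treatment_idx), pc),
                    error = function(e) NA_real_)
  if (is.na(z_obs)) return(fail("degenerate score statistic"))
  if (is.null(bank)) bank <- resample_bank(n, seed, paste0("n", n))

  o1 <- bank_range(bank, 1L, cfg$B1)
  z1 <- tryCatch(score_stats_permuted(pc, o1, t_),
                 error = function(e) conditionMessage(e))
  if (is.character(z1)) return(fail(z1))
  p1 <- empirical_p(z_obs, z1, cfg$side)

  stage <- 1L
  z_null <- z1
  if (p1 <= cfg$p_thresh) {
    stage <- 2L
    o2 <- bank_range(bank, cfg$B1 + 1L, cfg$B1 + cfg$B2)
    z2 <- tryCatch(score_stats_permuted(pc, o2, t_),
                   error = function(e) conditionMessage(e))
    if (is.character(z2)) return(fail(z2))
    z_null <- z2
  }
  sn_fit <- tryCatch(fit_mom(z_null), error = function(e) NULL)
  ps <- all_side_p(z_obs, z_null, sn_fit)
  structure(list(pair_id = pair_id, z_obs = z_obs, n_treatment = t_,
                 p_left = ps$left, p_right = ps$right, p_two = ps$two,
                 p_method = ps$method, stage = stage,
                 lfc = compute_lfc(Y, libsize, treatment_idx, control_idx),
                 sn_fit = sn_fit, qc_pass = TRUE, error = NULL),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat("pair_result", x$pair_id, ": z =", signif(x$z_obs, 4),
      ", p_two =", signif(x$p_two, 4), "(", x$p_method, ", stage",
      x$stage, ")\n")
  invisible(x)
}

#' Run a batch of perturbation-response pairs
#'
#' Applies [test_pair()] to every pair spec, building each pair's cell
#' universe per the control-group semantics (see [resolve_cells()]).
#' Null-model fits are cached per (response, universe) — the null GLM
#' does not involve the treatment label — and resample banks are shared
#' across pairs with identical universes, so results are independent of
#' pair order and of `workers`.
#'
#' @param ds a QC'd [screen_dataset()].
#' @param pairs data.frame of pair specs (see [make_pair_specs()]).
#' @param cfg an [adaptive_config()].
#' @param formula covariate names for [build_covariate_matrix()].
#' @param family GLM family for [fit_null_glm()].
#' @param seed global seed.
#' @param workers number of worker processes (results identical for any
#'   value; parallelism via `parallel::mclapply` over response groups).
#' @return data.frame with one row per pair: `pair_id`, `grna_group`,
#'   `response_id`, `n_treatment`, `ess`, `z_obs`, `lfc`, `p_left`,
#'   `p_right`, `p_two`, `p_method`, `stage`, `qc_pass`.
#' @export
run_batch <- function(ds, pairs, cfg = adaptive_config(),
                      formula = "library_size", family = "nb", seed = 1,
                      workers = 1) {
  Z_full <- build_covariate_matrix(ds, formula)
  libsize_full <- as.numeric(Matrix::colSums(ds$counts))
  cells <- ds$cell_ids
  counts <- ds$counts

  # universes depend only on (grna_group, control_group): resolve and
  # hash once per distinct combination
  combo <- paste(pairs$grna_group, pairs$control_group %||% "nt_cells")
  ucombos <- !duplicated(combo)
  res_by_combo <- lapply(which(ucombos), function(i)
    resolve_cells(ds, pairs[i, , drop = FALSE]))
  names(res_by_combo) <- combo[ucombos]
  key_by_combo <- vapply(res_by_combo, function(r)
    paste0("c", length(r$universe), "_",
           fnv1a_hash(paste(r$universe, collapse = ","))), "")
  resolved <- res_by_combo[combo]
  ukeys <- unname(key_by_combo[combo])
  pairs$pair_id <- paste(pairs$grna_group, pairs$response_id, sep = "|")
  # one shared resample bank per distinct cell universe, stage-1
  # orderings realized up front (before any forked worker copies it)
  banks <- new.env(parent = emptyenv())
  for (uk in unique(ukeys)) {
    i0 <- which(ukeys == uk)[1]
    banks[[uk]] <- resample_bank(length(resolved[[i0]]$universe), seed, uk)
    bank_orderings(banks[[uk]], cfg$B1)
  }
  groups <- split(seq_len(nrow(pairs)),
                  paste(pairs$response_id, ukeys, sep = "@"))

  run_group <- function(idx) {
    r0 <- resolved[[idx[1]]]
    uni <- r0$universe
    Y <- as.numeric(counts[pairs$response_id[idx[1]], uni])
    Z <- Z_full[uni, , drop = FALSE]
    bank <- banks[[ukeys[idx[1]]]]
    lapply(idx, function(i) {
      r <- resolved[[i]]
      tr <- match(r$treatment, uni)
      ct <- match(r$control, uni)
      ess <- sum(Y[tr] > 0)
      res <- if (length(tr) == 0 || length(ct) == 0) {
        structure(list(pair_id = pairs$pair_id[i], z_obs = NA_real_,
                       n_treatment = length(tr), p_left = 1, p_right = 1,
                       p_two = 1, p_method = "none", stage = 0L,
                       lfc = NA_real_, sn_fit = NULL, qc_pass = FALSE,
                       error = "empty treatment or control"),
                  class = "pair_result")
      } else {
        test_pair(Y, Z, tr, ct, cfg = cfg, family = family, seed = seed,
                  bank = bank, pair_id = pairs$pair_id[i],
                  libsize = libsize_full[uni])
      }
      data.frame(pair_id = res$pair_id,
                 grna_group = pairs$grna_group[i],
                 response_id = pairs$response_id[i],
                 n_treatment = res$n_treatment, ess = ess,
                 z_obs = res$z_obs, lfc = res$lfc,
                 p_left = res$p_left, p_right = res$p_right,
                 p_two = res$p_two, p_method = res$p_method,
                 stage = res$stage, qc_pass = res$qc_pass)
    })
  }

  out <- if (workers > 1) {
    parallel::mclapply(groups, run_group, mc.cores = workers)
  } else {
    lapply(groups, run_group)
  }
  res <- do.call(rbind, unlist(out, recursive = FALSE))
  res <- res[match(pairs$pair_id, res$pair_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write batch results and a reproducibility manifest
#'
#' @param results data.frame from [run_batch()].
#' @param dir output directory.
#' @param meta named list folded into the JSON manifest (seed, config,
#'   filter report, ...).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(results, file.path(dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta$package_version <- as.character(utils::packageVersion("screenperm"))
  jsonlite::write_json(meta, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
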