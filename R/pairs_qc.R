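#' Construct pair specifications
#'
#' A pair spec couples a gRNA group to a response, with a pair type and
#' control-group semantics. `control_group = "nt_cells"` compares a
#' group's cells against the remaining non-targeting (NT) cells — for a
#' negative-control pair on NT gRNA i this is exactly C_i versus
#' C \ C_i, the NT cells excluding gRNA i. `"complement"` compares
#' against all other cells.
#'
#' @param grna_group character vector of gRNA group identifiers.
#' @param response_id character vector (recycled against `grna_group`).
#' @param pair_type `"discovery"`, `"negative_control"`, or
#'   `"positive_control"`.
#' @param control_group `"nt_cells"` or `"complement"`.
#' @return data.frame of pair specs.
#' @export
make_pair_specs <- function(grna_group, response_id,
                            pair_type = "discovery",
                            control_group = "nt_cells") {
  stopifnot(control_group %in% c("nt_cells", "complement"),
            pair_type %in% c("discovery", "negative_control",
                             "positive_control"))
  data.frame(grna_group = as.character(grna_group),
             response_id = as.character(response_id),
             pair_type = pair_type, control_group = control_group,
             stringsAsFactors = FALSE)
}

# Map from gRNA group id to the cell indices (in ds$cell_ids order)
# carrying any gRNA of that group.
group_cells <- function(ds, group) {
  gids <- ds$grna_table$grna_id[ds$grna_table$grna_group == group]
  if (length(gids) == 0) stop("unknown gRNA group: ", group)
  asn <- ds$grna_assignment
  sort(match(unique(asn$cell_id[asn$grna_id %in% gids]), ds$cell_ids))
}

nt_cells <- function(ds) {
  nt_ids <- ds$grna_table$grna_id[!ds$grna_table$targeting]
  asn <- ds$grna_assignment
  sort(match(unique(asn$cell_id[asn$grna_id %in% nt_ids]), ds$cell_ids))
}

#' Resolve a pair's treatment and control cells
#'
#' NT-cells mode: treatment = the spec's group cells; control = all NT
#' cells minus the treatment. Complement mode: control = all other
#' cells. Sets are disjoint sorted index vectors into `ds$cell_ids`.
#'
#' @param ds a [screen_dataset()].
#' @param spec one-row pair spec data.frame.
#' @return list with `treatment`, `control`, and `universe` (their
#'   sorted union).
#' @export
resolve_cells <- function(ds, spec) {
  tr <- group_cells(ds, spec$grna_group)
  ct <- if (spec$control_group == "nt_cells") {
    setdiff(nt_cells(ds), tr)
  } else {
    setdiff(seq_along(ds$cell_ids), tr)
  }
  list(treatment = tr, control = ct, universe = sort(c(tr, ct)))
}

#' Effective sample size of a pair
#'
#' The number of cells containing both the perturbation and nonzero
#' expression of the response — the quantity that drives both the
#' calibration and the power of sparse-count association tests.
#'
#' @param ds a [screen_dataset()].
#' @param spec one-row pair spec.
#' @return integer.
#' @export
effective_sample_size <- function(ds, spec) {
  tr <- group_cells(ds, spec$grna_group)
  sum(ds$counts[spec$response_id, tr] > 0)
}

#' Pairwise quality control
#'
#' Keeps pairs whose effective sample size is at least `ess_min`
#' (default 7, below which calibration and power both degrade).
#' Unresolvable pairs (unknown group/response, empty treatment or
#' control) are removed with a reason.
#'
#' @param pairs pair-spec data.frame.
#' @param ds a [screen_dataset()].
#' @param ess_min minimum effective sample size.
#' @return list with `kept` (pair specs + `ess` column) and `removed`
#'   (pair specs + `reason`).
#' @export
pairwise_qc <- function(pairs, ds, ess_min = 7) {
  reasons <- character(nrow(pairs))
  ess <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sp <- pairs[i, , drop = FALSE]
    if (!sp$response_id %in% ds$response_ids) {
      reasons[i] <- "unknown response"
      next
    }
    rc <- tryCatch(resolve_cells(ds, sp), error = function(e) NULL)
    if (is.null(rc)) {
      reasons[i] <- "unknown gRNA group"
      next
    }
    if (length(rc$treatment) == 0 || length(rc$control) == 0) {
      reasons[i] <- "empty treatment or control"
      next
    }
    ess[i] <- effective_sample_size(ds, sp)
    if (ess[i] < ess_min) reasons[i] <- "ess below threshold"
  }
  keep <- reasons == ""
  kept <- pairs[keep, , drop = FALSE]
  kept$ess <- ess[keep]
  removed <- pairs[!keep, , drop = FALSE]
  removed$reason <- reasons[!keep]
  if (nrow(removed) > 0) removed$ess <- ess[!keep]
  list(kept = kept, removed = removed)
}

#' Automatically construct matched negative-control pairs
#'
#' Candidates are all (NT gRNA or NT gRNA group) x response pairs. The
#' candidates receive the same pairwise QC as the discovery pairs; if
#' more candidates survive than there are discovery pairs, a uniform
#' without-replacement seeded subsample brings the count down to match.
#' When `grouped = TRUE`, NT gRNAs are randomly partitioned (seeded)
#' into groups whose size distribution matches the discovery groups'
#' sizes, mirroring a grouped discovery analysis.
#'
#' @param ds a [screen_dataset()].
#' @param discovery_pairs QC'd discovery pair specs (their count is the
#'   matching target).
#' @param ess_min pairwise QC threshold (must equal the discovery one).
#' @param grouped partition NT gRNAs into discovery-sized groups.
#' @param seed integer seed for the partition and the subsample.
#' @param control_group control-group semantics for the pairs.
#' @return pair-spec data.frame with `ess` column (post-QC).
#' @export
build_negative_control_pairs <- function(ds, discovery_pairs, ess_min = 7,
                                         grouped = FALSE, seed = 1,
                                         control_group = "nt_cells") {
  nt <- ds$grna_table[!ds$grna_table$targeting, , drop = FALSE]
  if (nrow(nt) < 2 && control_group == "nt_cells")
    stop("need at least 2 NT gRNAs for NT-cells control group")
  if (nrow(nt) == 0) stop("no NT gRNAs in dataset")
  ds2 <- ds
  if (grouped) {
    sizes <- table(discovery_pairs$grna_group)  # placeholder sizes
    dsizes <- as.integer(table(
      ds$grna_table$grna_group[ds$grna_table$targeting]))
    set.seed(derive_seed(seed, "nt_grouping"))
    perm <- sample(nt$grna_id)
    groups <- character(0)
    i <- 1
    g <- 1
    szpool <- if (length(dsizes) > 0) dsizes else 1L
    while (i <= length(perm)) {
      k <- szpool[(g - 1) %% length(szpool) + 1]
      groups <- c(groups, rep(paste0("ntgroup_", g),
                              min(k, length(perm) - i + 1)))
      i <- i + k
      g <- g + 1
    }
    map <- stats::setNames(groups, perm)
    ds2$grna_table$grna_group[!ds2$grna_table$targeting] <-
      map[ds2$grna_table$grna_id[!ds2$grna_table$targeting]]
    nt_groups <- unique(groups)
  } else {
    nt_groups <- nt$grna_group
  }
  cand <- make_pair_specs(
    grna_group = rep(nt_groups, times = length(ds$response_ids)),
    response_id = rep(ds$response_ids, each = length(nt_groups)),
    pair_type = "negative_control", control_group = control_group)
  qc <- pairwise_qc(cand, ds2, ess_min = ess_min)
  kept <- qc$kept
  n_target <- nrow(discovery_pairs)
  if (nrow(kept) > n_target) {
    set.seed(derive_seed(seed, "nc_subsample"))
    kept <- kept[sort(sample.int(nrow(kept), n_target)), , drop = FALSE]
  } else if (nrow(kept) < n_target) {
    warning("only ", nrow(kept), " negative-control candidates survive QC (",
            n_target, " requested); returning all")
  }
  attr(kept, "grouped_dataset") <- if (grouped) ds2 else NULL
  kept
}

#' Construct positive-control pairs from gRNA target labels
#'
#' One pair per targeting gRNA group whose target label (case
#' normalized, exact match) equals a response id. Ambiguous labels
#' (matching several responses after normalization) are an error.
#'
#' @param ds a [screen_dataset()].
#' @param control_group control-group semantics.
#' @return pair-spec data.frame (possibly empty, with a warning).
#' @export
build_positive_control_pairs <- function(ds, control_group = "nt_cells") {
  gt <- ds$grna_table[ds$grna_table$targeting, , drop = FALSE]
  groups <- unique(gt$grna_group)
  resp_norm <- toupper(ds$response_ids)
  out <- list()
  for (g in groups) {
    targ <- unique(toupper(gt$target[gt$grna_group == g]))
    targ <- targ[targ %in% resp_norm]
    if (length(targ) == 0) next
    for (tg in targ) {
      hits <- ds$response_ids[resp_norm == tg]
      if (length(hits) > 1)
        stop("ambiguous target label ", tg, " matches multiple responses")
      out[[length(out) + 1]] <- make_pair_specs(
        g, hits, pair_type = "positive_control",
        control_group = control_group)
    }
  }
  if (length(out) == 0) {
    warning("no gRNA target labels match any response id")
    return(make_pair_specs(character(0), character(0),
                           "positive_control", control_group))
  }
  do.call(rbind, out)
}
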