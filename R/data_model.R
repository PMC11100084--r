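#' Screen dataset container
#'
#' A `screen_dataset` bundles the state of a low-MOI single-cell CRISPR
#' screen: the raw UMI count matrix (responses in rows, cells in columns),
#' the gRNA-to-cell assignment, per-gRNA metadata, and per-cell technical
#' covariates. Low MOI means each retained cell carries exactly one gRNA
#' (cells with zero or multiple gRNAs are removed by [apply_dataset_qc()]).
#'
#' @param counts response-by-cell matrix of nonnegative integer UMI counts.
#'   A base matrix or any [Matrix::sparseMatrix()]; stored as `dgCMatrix`.
#' @param response_ids character vector of row identifiers (genes/proteins).
#' @param cell_ids character vector of column identifiers.
#' @param grna_assignment data.frame with columns `cell_id`, `grna_id`.
#'   One row per (cell, gRNA); multiple rows per cell are permitted until
#'   QC enforces single-gRNA cells.
#' @param grna_table data.frame with columns `grna_id`, `target`,
#'   `targeting` (logical), `grna_group`.
#' @param covariates data.frame of per-cell technical factors, one row per
#'   cell (row order matching `cell_ids`), or `NULL`.
#'
#' @return an object of class `screen_dataset` with fields `counts`,
#'   `response_ids`, `cell_ids`, `grna_assignment`, `grna_table`,
#'   `covariates`, and `qc_report` (filled in by [apply_dataset_qc()]).
#' @export
screen_dataset <- function(counts, response_ids, cell_ids, grna_assignment,
                           grna_table, covariates = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(response_ids) != nrow(counts))
    stop("dimension error: length(response_ids) != nrow(counts)")
  if (length(cell_ids) != ncol(counts))
    stop("dimension error: length(cell_ids) != ncol(counts)")
  dimnames(counts) <- list(as.character(response_ids), as.character(cell_ids))
  ds <- structure(list(
    counts = counts,
    response_ids = as.character(response_ids),
    cell_ids = as.character(cell_ids),
    grna_assignment = grna_assignment,
    grna_table = grna_table,
    covariates = covariates,
    qc_report = NULL
  ), class = "screen_dataset")
  validate_screen_dataset(ds)
}

validate_screen_dataset <- function(ds) {
  stopifnot(inherits(ds, "screen_dataset"))
  if (any(ds$counts@x < 0))
    stop("format error: counts matrix has negative entries")
  asn <- ds$grna_assignment
  if (!all(c("cell_id", "grna_id") %in% names(asn)))
    stop("format error: grna_assignment needs columns cell_id, grna_id")
  unknown <- setdiff(asn$cell_id, ds$cell_ids)
  if (length(unknown) > 0)
    stop("dimension error: ", length(unknown),
         " assignment cell_ids absent from counts (e.g. ", unknown[1], ")")
  gt <- ds$grna_table
  need <- c("grna_id", "target", "targeting", "grna_group")
  if (!all(need %in% names(gt)))
    stop("format error: grna_table needs columns ",
         paste(need, collapse = ", "))
  bad <- setdiff(asn$grna_id, gt$grna_id)
  if (length(bad) > 0)
    stop("format error: assignment references unknown gRNA ids (e.g. ",
         bad[1], ")")
  if (!is.null(ds$covariates)) {
    if (nrow(ds$covariates) != length(ds$cell_ids))
      stop("dimension error: covariate rows must align with cell_ids")
  }
  ds
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:", nrow(x$counts), "responses x", ncol(x$counts),
      "cells;", nrow(x$grna_table), "gRNAs (",
      sum(x$grna_table$targeting), "targeting,",
      sum(!x$grna_table$targeting), "non-targeting )\n")
  if (!is.null(x$qc_report)) cat("  QC applied:",
      paste(names(x$qc_report$removed), x$qc_report$removed,
            sep = "=", collapse = ", "), "removed\n")
  invisible(x)
}

#' Dataset-level QC thresholds
#'
#' Defaults follow the uniform minimal QC used throughout: genes expressed
#' in at least a fraction 0.005 of cells, gRNAs present in at least 10
#' cells, and cells carrying exactly one gRNA.
#'
#' @param min_gene_frac fraction in `[0,1]` of cells in which a gene must
#'   be nonzero to be retained.
#' @param min_cells_per_grna minimum number of cells per retained gRNA.
#' @param require_single_grna drop cells with zero or multiple gRNAs.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gene_frac = 0.005, min_cells_per_grna = 10,
                          require_single_grna = TRUE) {
  stopifnot(min_gene_frac >= 0, min_gene_frac <= 1, min_cells_per_grna >= 0)
  structure(list(min_gene_frac = min_gene_frac,
                 min_cells_per_grna = min_cells_per_grna,
                 require_single_grna = require_single_grna),
            class = "qc_thresholds")
}

#' Apply dataset-level quality control
#'
#' Filters, in order: (1) cells with exactly one assigned gRNA (cells with
#' no assignment are always dropped); (2) genes expressed in at least
#' `min_gene_frac` of the retained cells; (3) gRNAs present in at least
#' `min_cells_per_grna` retained cells (their cells are dropped too).
#' Cells are filtered first so that gene expression fractions refer to
#' retained cells. The operation is idempotent.
#'
#' @param ds a [screen_dataset()].
#' @param thr a [qc_thresholds()].
#' @return the filtered `screen_dataset`, with a `qc_report` listing the
#'   number of cells/genes/gRNAs removed per step.
#' @export
apply_dataset_qc <- function(ds, thr = qc_thresholds()) {
  validate_screen_dataset(ds)
  asn <- ds$grna_assignment
  tab <- table(asn$cell_id)
  keep_cells <- if (thr$require_single_grna) {
    names(tab)[tab == 1L]
  } else {
    names(tab)
  }
  keep_cells <- intersect(ds$cell_ids, keep_cells)  # preserve file order
  n_cells_removed <- length(ds$cell_ids) - length(keep_cells)
  if (length(keep_cells) == 0L) stop("empty-dataset error: all cells removed")
  counts <- ds$counts[, keep_cells, drop = FALSE]

  frac_expressed <- Matrix::rowSums(counts > 0) / ncol(counts)
  keep_genes <- ds$response_ids[frac_expressed >= thr$min_gene_frac]
  n_genes_removed <- nrow(counts) - length(keep_genes)
  counts <- counts[keep_genes, , drop = FALSE]

  asn <- asn[asn$cell_id %in% keep_cells, , drop = FALSE]
  grna_sizes <- table(asn$grna_id)
  keep_grnas <- names(grna_sizes)[grna_sizes >= thr$min_cells_per_grna]
  n_grnas_removed <- nrow(ds$grna_table) - length(keep_grnas)
  asn <- asn[asn$grna_id %in% keep_grnas, , drop = FALSE]
  keep_cells2 <- intersect(keep_cells, asn$cell_id)
  if (length(keep_cells2) == 0L) stop("empty-dataset error: all cells removed")
  counts <- counts[, keep_cells2, drop = FALSE]
  cov <- ds$covariates
  if (!is.null(cov)) {
    rownames(cov) <- ds$cell_ids
    cov <- cov[keep_cells2, , drop = FALSE]
  }
  out <- structure(list(
    counts = counts,
    response_ids = keep_genes,
    cell_ids = keep_cells2,
    grna_assignment = asn,
    grna_table = ds$grna_table[ds$grna_table$grna_id %in% keep_grnas, ,
                               drop = FALSE],
    covariates = cov,
    qc_report = list(
      thresholds = thr,
      removed = c(cells = n_cells_removed +
                    (length(keep_cells) - length(keep_cells2)),
                  genes = n_genes_removed,
                  grnas = n_grnas_removed))
  ), class = "screen_dataset")
  validate_screen_dataset(out)
}

#' Read a screen dataset from disk
#'
#' Counts may be either MatrixMarket coordinate format (`.mtx`) with
#' sidecar files `response_ids.txt` and `cell_ids.txt` (one id per line,
#' located next to the mtx file), or a dense TSV whose header row holds
#' cell ids and whose first column holds response ids. The three tables
#' are tab-separated with a header. Cells present in the counts but
#' absent from the assignment are dropped (with a logged count).
#'
#' @param counts_path path to `.mtx` or dense `.tsv` counts.
#' @param grna_path TSV with columns `cell_id`, `grna_id`.
#' @param grna_meta_path TSV with columns `grna_id`, `target`,
#'   `targeting`, `grna_group`.
#' @param covariates_path optional TSV keyed by a `cell_id` column.
#' @return a validated [screen_dataset()].
#' @export
read_dataset <- function(counts_path, grna_path, grna_meta_path,
                         covariates_path = NULL) {
  for (f in c(counts_path, grna_path, grna_meta_path, covariates_path)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  }
  if (grepl("\\.mtx$", counts_path)) {
    counts <- tryCatch(Matrix::readMM(counts_path), error = function(e)
      stop("format error in ", counts_path, ": ", conditionMessage(e)))
    side <- dirname(counts_path)
    response_ids <- readLines(file.path(side, "response_ids.txt"))
    cell_ids <- readLines(file.path(side, "cell_ids.txt"))
    if (length(response_ids) != nrow(counts) ||
        length(cell_ids) != ncol(counts))
      stop("dimension error: sidecar id files do not match mtx dimensions")
  } else {
    tab <- read.delim(counts_path, check.names = FALSE)
    response_ids <- as.character(tab[[1]])
    counts <- as.matrix(tab[, -1, drop = FALSE])
    cell_ids <- colnames(counts)
  }
  if (any(counts < 0))
    stop("format error in ", counts_path, ": negative count entry")
  asn <- read.delim(grna_path, colClasses = "character")
  gt <- read.delim(grna_meta_path)
  gt$grna_id <- as.character(gt$grna_id)
  gt$targeting <- as.logical(gt$targeting)
  cov <- NULL
  keep <- intersect(cell_ids, asn$cell_id)
  dropped <- length(cell_ids) - length(keep)
  if (dropped > 0) {
    sp_log(dropped, " cells in counts had no gRNA assignment; dropped")
    ci <- match(keep, cell_ids)
    counts <- counts[, ci, drop = FALSE]
    cell_ids <- keep
  }
  if (!is.null(covariates_path)) {
    cov <- read.delim(covariates_path)
    if (!"cell_id" %in% names(cov))
      stop("format error in ", covariates_path, ": no cell_id column")
    cov$cell_id <- as.character(cov$cell_id)
    m <- match(cell_ids, cov$cell_id)
    if (anyNA(m))
      stop("dimension error: covariate table missing cells (e.g. ",
           cell_ids[which(is.na(m))[1]], ")")
    cov <- cov[m, setdiff(names(cov), "cell_id"), drop = FALSE]
    rownames(cov) <- cell_ids
  }
  screen_dataset(counts, response_ids, cell_ids, asn, gt, cov)
}

#' Write a screen dataset to disk
#'
#' Emits the same dialects that [read_dataset()] accepts: MatrixMarket
#' counts with id sidecars (or a dense TSV if `dense = TRUE`), plus
#' `grna_assignment.tsv`, `grna_table.tsv`, and `covariates.tsv`.
#'
#' @param ds a [screen_dataset()].
#' @param dir output directory (created if needed).
#' @param dense write counts as dense TSV instead of MTX.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, dense = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (dense) {
    tab <- data.frame(response_id = ds$response_ids,
                      as.matrix(ds$counts), check.names = FALSE)
    colnames(tab) <- c("response_id", ds$cell_ids)
    write.table(tab, file.path(dir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    m <- ds$counts
    dimnames(m) <- NULL
    Matrix::writeMM(m, file.path(dir, "counts.mtx"))
    writeLines(ds$response_ids, file.path(dir, "response_ids.txt"))
    writeLines(ds$cell_ids, file.path(dir, "cell_ids.txt"))
  }
  write.table(ds$grna_assignment, file.path(dir, "grna_assignment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$grna_table, file.path(dir, "grna_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$covariates)) {
    cov <- data.frame(cell_id = ds$cell_ids, ds$covariates,
                      check.names = FALSE)
    write.table(cov, file.path(dir, "covariates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Build the technical-covariate design matrix Z
#'
#' Assembles the cell-by-term matrix used by the null GLM. An intercept
#' column of ones is always included. Numeric covariates are
#' log-transformed (natural log; values must be positive, which holds for
#' library sizes and genes-expressed counts after QC). Categorical
#' covariates are expanded to reference-coded indicator columns. A
#' `library_size` term is computed from the counts when not supplied in
#' the covariate table.
#'
#' @param ds a [screen_dataset()].
#' @param formula character vector of covariate names; the special name
#'   `"library_size"` is always available.
#' @return numeric matrix with one row per cell and full column rank.
#' @export
build_covariate_matrix <- function(ds, formula = c("library_size")) {
  n <- length(ds$cell_ids)
  cols <- list(intercept = rep(1, n))
  for (f in formula) {
    if (f == "library_size" &&
        !(f %in% names(ds$covariates %||% list()))) {
      # floor at 1 UMI so empty-transcriptome cells (possible in tiny
      # fixtures) do not break the log transform
      v <- pmax(as.numeric(Matrix::colSums(ds$counts)), 1)
    } else {
      if (!f %in% names(ds$covariates))
        stop("unknown covariate: ", f)
      v <- ds$covariates[[f]]
    }
    if (is.numeric(v)) {
      if (any(v <= 0))
        stop("covariate ", f, " must be positive for log transform")
      cols[[f]] <- log(v)
    } else {
      fv <- factor(v)
      if (nlevels(fv) < 2)
        stop("collinearity error: categorical covariate ", f,
             " has fewer than 2 observed levels")
      mm <- model.matrix(~fv)[, -1, drop = FALSE]
      colnames(mm) <- paste0(f, "_", levels(fv)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- ds$cell_ids
  nonconst <- apply(Z[, -1, drop = FALSE], 2, function(x) var(x) > 0)
  if (ncol(Z) > 1 && any(!nonconst))
    stop("collinearity error: constant covariate column ",
         colnames(Z)[-1][!nonconst][1])
  if (qr(Z)$rank < ncol(Z))
    stop("collinearity error: covariate matrix is rank deficient")
  Z
}
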