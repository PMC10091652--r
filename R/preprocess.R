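## Normalization, gene filtering, HVG selection, per-patient mean profiles.

#' Construct a cell expression container
#'
#' Genes x cells matrix of log-normalized expression plus per-cell and
#' per-patient covariates; the substrate of every pipeline stage.
#'
#' @param values genes x cells numeric matrix (log2 scale, finite, >= 0).
#' @param cells data.frame with at least cell_id, patient_id, diagnosis,
#'   cell_type; rows aligned with matrix columns.
#' @param patients data.frame with patient_id plus covariates (age, sex,
#'   RIN, PMI, region).
#' @return object of class \code{cell_expr}.
#' @export
cell_expr <- function(values, cells, patients) {
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(cells$cell_id)) stopf("duplicate cell ids")
  if (!identical(colnames(values), cells$cell_id))
    stopf("matrix columns and cell metadata rows disagree")
  orphan <- setdiff(unique(cells$patient_id), patients$patient_id)
  if (length(orphan))
    stopf("cells reference patients without metadata: %s",
          paste(head(orphan, 3), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stopf("expression values must be finite and nonnegative")
  structure(list(values = values, cells = cells, patients = patients),
            class = "cell_expr")
}

#' Library-size normalize and log2-transform a count matrix
#'
#' Size factor s_c = library size of cell c / median library size; values
#' are log2(count / s_c + 1). Per-cell detection rate (fraction of genes
#' with count > 0) is recomputed and stored in the cell metadata.
#'
#' @param counts genes x cells nonnegative integer matrix (dense or sparse).
#' @param cells,patients metadata as for \code{\link{cell_expr}}.
#' @return a \code{\link{cell_expr}}.
#' @export
normalize_log <- function(counts, cells, patients) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stopf("cell(s) with zero library size: %s",
          paste(head(colnames(counts)[lib == 0], 3), collapse = ", "))
  s <- lib / median(lib)
  dense <- as.matrix(counts)
  values <- log2(sweep(dense, 2, s, "/") + 1)
  cells$detection_rate <- Matrix::colSums(counts > 0) / nrow(counts)
  cell_expr(values, cells, patients)
}

#' Select highly variable genes
#'
#' Removes genes matching any exclusion regex, ranks the remainder by
#' variance of log expression across cells and keeps the top \code{n_top},
#' preserving the original gene order within the kept set.
#'
#' @param expr a \code{\link{cell_expr}}.
#' @param n_top number of genes to keep.
#' @param exclude_patterns character vector of gene-id regexes removed
#'   before ranking (default mitochondrial and ribosomal-protein prefixes).
#' @return a \code{\link{cell_expr}} restricted to the selected genes.
#' @export
select_hvg <- function(expr, n_top,
                       exclude_patterns = c("^MT-", "^RP[LS]")) {
  stopifnot(inherits(expr, "cell_expr"))
  ids <- rownames(expr$values)
  drop <- rep(FALSE, length(ids))
  for (pat in exclude_patterns) drop <- drop | grepl(pat, ids)
  keep_ids <- ids[!drop]
  if (n_top > length(keep_ids))
    stopf("n_top (%d) exceeds the %d genes left after exclusion",
          n_top, length(keep_ids))
  v <- apply(expr$values[keep_ids, , drop = FALSE], 1, var)
  top <- names(sort(v, decreasing = TRUE))[seq_len(n_top)]
  sel <- ids[ids %in% top]          # original order preserved
  expr$values <- expr$values[sel, , drop = FALSE]
  expr
}

#' Per-patient mean profiles within one cell type
#'
#' Row p is the arithmetic mean of patient p's cells of the given cell type;
#' patients with no such cells are omitted with a warning.
#'
#' @param expr a \code{\link{cell_expr}} or a \code{set_scores} object.
#' @param cell_type cell-type label to average within; NULL uses all cells.
#' @return patients x features numeric matrix.
#' @export
patient_mean_profiles <- function(expr, cell_type = NULL) {
  if (inherits(expr, "set_scores")) {
    values <- expr$values
    cells <- expr$cells
  } else {
    stopifnot(inherits(expr, "cell_expr"))
    values <- expr$values
    cells <- expr$cells
  }
  universe <- unique(cells$patient_id)
  if (!is.null(cell_type)) {
    keep <- cells$cell_type == cell_type
    values <- values[, keep, drop = FALSE]
    cells <- cells[keep, , drop = FALSE]
  }
  if (ncol(values) == 0) stopf("no cells to average")
  pats <- unique(cells$patient_id)
  absent <- setdiff(universe, pats)
  if (length(absent))
    warnf("%d patient(s) with no cells of type '%s' omitted: %s",
          length(absent), cell_type, paste(head(absent, 3), collapse = ", "))
  out <- t(vapply(pats, function(p)
    rowMeans(values[, cells$patient_id == p, drop = FALSE]),
    numeric(nrow(values))))
  rownames(out) <- pats
  colnames(out) <- rownames(values)
  out
}
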