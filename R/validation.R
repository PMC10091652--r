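## Cross-dataset subtype correspondence: per-subtype fold-change signatures
## and their Pearson correlation across independently subtyped datasets.

#' Per-subtype fold changes versus the other subtypes
#'
#' Individual-level mean log2 expression per gene (optionally combining all
#' cell types per individual first), then subtype group mean minus the mean
#' of the remaining subtypes.
#'
#' @param values genes x cells (or genes x samples) matrix.
#' @param sample_patient patient id per column.
#' @param labels named subtype label per patient (>= 2 subtypes).
#' @return genes x subtypes matrix of fold changes.
#' @export
subtype_fold_changes <- function(values, sample_patient, labels) {
  labs <- labels[!is.na(labels)]
  if (length(unique(labs)) < 2) stopf("need at least 2 subtypes")
  pats <- intersect(unique(sample_patient), names(labs))
  ind_means <- vapply(pats, function(p)
    rowMeans(values[, sample_patient == p, drop = FALSE]),
    numeric(nrow(values)))
  subs <- sort(unique(labs[pats]))
  sizes <- table(labs[pats])
  if (any(sizes == 1))
    warnf("subtype(s) with a single individual: %s",
          paste(names(sizes)[sizes == 1], collapse = ", "))
  fc <- vapply(subs, function(s) {
    inn <- pats[labs[pats] == s]
    out <- pats[labs[pats] != s]
    rowMeans(ind_means[, inn, drop = FALSE]) -
      rowMeans(ind_means[, out, drop = FALSE])
  }, numeric(nrow(values)))
  rownames(fc) <- rownames(values)
  colnames(fc) <- as.character(subs)
  fc
}

#' Correspondence between two subtype systems
#'
#' Pearson correlation (and p-value) between every pair of fold-change
#' signatures over the shared gene universe.
#'
#' @param fc_sn genes x k1 fold changes (e.g. single-nucleus subtypes).
#' @param fc_bulk genes x k2 fold changes (e.g. bulk subtypes).
#' @return list with \code{r}, \code{p} (k1 x k2 matrices) and
#'   \code{n_shared}.
#' @export
correspondence_matrix <- function(fc_sn, fc_bulk) {
  shared <- intersect(rownames(fc_sn), rownames(fc_bulk))
  if (length(shared) < 3) stopf("fewer than 3 shared genes")
  a <- fc_sn[shared, , drop = FALSE]
  b <- fc_bulk[shared, , drop = FALSE]
  r <- matrix(NA_real_, ncol(a), ncol(b),
              dimnames = list(colnames(a), colnames(b)))
  p <- r
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    if (var(a[, i]) == 0 || var(b[, j]) == 0) {
      warnf("zero-variance fold-change vector; NA correspondence entry")
      next
    }
    ct <- cor.test(a[, i], b[, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n_shared = length(shared))
}

#' Subtype a bulk expression matrix with the same two-modality pipeline
#'
#' Treats the bulk matrix as a single "cell type": scores gene sets per
#' sample, builds one affinity view from genes and one from set scores,
#' fuses them and clusters — the single-view-pair special case of the
#' two-level fusion.
#'
#' @param bulk patients x genes matrix (log scale).
#' @param sets gene-set collection.
#' @param gsva_par a \code{\link{gsva_params}}.
#' @param snf_par an \code{\link{snf_params}}.
#' @param k optional fixed cluster number.
#' @return a \code{subtype_assignment} (see \code{\link{subtype_patients}}).
#' @export
bulk_subtypes <- function(bulk, sets, gsva_par = gsva_params(),
                          snf_par = snf_params(), k = NULL) {
  pseudo_cells <- data.frame(cell_id = rownames(bulk),
                             patient_id = rownames(bulk),
                             diagnosis = "case", cell_type = "bulk",
                             stringsAsFactors = FALSE)
  pseudo_pat <- data.frame(patient_id = rownames(bulk),
                           stringsAsFactors = FALSE)
  expr <- cell_expr(t(bulk), pseudo_cells, pseudo_pat)
  scores <- gsva_scores(expr, sets, gsva_par)
  fused <- fuse_views(list(genes = bulk, sets = t(scores$values)), snf_par)
  subtype_patients(fused, snf_par, k = k)
}
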