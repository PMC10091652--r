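## Plain-text I/O: MatrixMarket counts, GMT gene sets, TSV tables, JSON truth.
## All formats round-trip losslessly; readers fail with the offending line.

#' Read a MatrixMarket coordinate file
#'
#' @param path .mtx file (coordinate dialect, 1-based, genes as rows).
#' @param gene_ids,cell_ids optional dimnames.
#' @return a sparse dgCMatrix.
#' @export
read_mtx <- function(path, gene_ids = NULL, cell_ids = NULL) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  if (!is.null(gene_ids)) {
    if (length(gene_ids) != nrow(m))
      stopf("%d gene ids for %d matrix rows", length(gene_ids), nrow(m))
    rownames(m) <- gene_ids
  }
  if (!is.null(cell_ids)) {
    if (length(cell_ids) != ncol(m))
      stopf("%d cell ids for %d matrix columns", length(cell_ids), ncol(m))
    colnames(m) <- cell_ids
  }
  m
}

#' Write a sparse count matrix as MatrixMarket integer coordinate
#'
#' @param m matrix or Matrix (genes x cells, nonnegative integers).
#' @param path output path.
#' @export
write_mtx <- function(m, path) {
  tm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                    "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated \code{name, description,
#' member...}; at least three fields per line.
#'
#' @param path GMT file.
#' @return named list of member vectors with a \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stopf("GMT line %d has fewer than 3 tab-separated fields", bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in GMT")
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(paste(names(sets), descriptions,
                   vapply(sets, paste, "", collapse = "\t"), sep = "\t"),
             path)
  invisible(path)
}

#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read the per-patient clinical score table
#'
#' @param path TSV with columns patient_id, A, B_verbal, B_nonverbal, C, D.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  need <- c("patient_id", "A", "B_verbal", "B_nonverbal", "C", "D")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("clinical table lacks column(s): %s", paste(missing, collapse = ", "))
  df
}

#' Read a gene list (one id per line)
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- sub("\r$", "", readLines(path))
  unique(x[nzchar(x)])
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory produced by \code{\link{write_cohort}}.
#' @return a list with the same shape as a \code{\link{simulate_cohort}}
#'   result (truth restored from JSON when present).
#' @export
read_cohort <- function(dir) {
  genes <- read_tsv(file.path(dir, "genes.tsv"))$gene_id
  patients <- read_tsv(file.path(dir, "patients.tsv"))
  cell_files <- list.files(dir, pattern = "_cells\\.tsv$", full.names = TRUE)
  counts <- list()
  cells <- list()
  for (cf in cell_files) {
    tag <- sub("_cells\\.tsv$", "", basename(cf))
    cdf <- read_tsv(cf)
    m <- read_mtx(file.path(dir, paste0(tag, "_counts.mtx")),
                  gene_ids = genes, cell_ids = cdf$cell_id)
    ct <- cdf$cell_type[1]
    counts[[ct]] <- m
    cells[[ct]] <- cdf
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path)) read_clinical(clin_path) else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(counts = counts, cells = cells, patients = patients,
                 gene_ids = genes, sets = sets, clinical = clinical,
                 truth = truth),
            class = "sim_cohort")
}
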