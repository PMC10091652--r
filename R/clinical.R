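## Clinical-score construction and association: combined rank score,
## patient-level fold changes, per-gene Pearson correlation, Fisher meta-P,
## per-category rank t-tests, hypergeometric risk-gene enrichment.

#' Clinical association parameters
#' @param min_degs minimum subtype-specific DEGs for a cell type to enter
#'   the meta-correlation (others reported NA).
#' @param min_degs_small relaxed filter applied to subtypes listed in
#'   \code{small_filter_subtypes}.
#' @param meta_alpha significance threshold on the meta P-value.
#' @param small_filter_subtypes subtypes the relaxed filter applies to.
#' @return list of class \code{clinical_params}.
#' @export
clinical_params <- function(min_degs = 10L, min_degs_small = 5L,
                            meta_alpha = 0.1, small_filter_subtypes = NULL) {
  if (min_degs_small > min_degs) stopf("min_degs_small must be <= min_degs")
  structure(list(min_degs = as.integer(min_degs),
                 min_degs_small = as.integer(min_degs_small),
                 meta_alpha = meta_alpha,
                 small_filter_subtypes = small_filter_subtypes),
            class = "clinical_params")
}

#' Combined clinical score: mean of within-category ranks
#'
#' Scores are ranked among patients with non-missing values in each category
#' (average ties) and each patient's combined score is the mean of their
#' category ranks over the categories they have.
#'
#' @param raw data.frame: patient_id plus numeric category columns.
#' @return named numeric vector of combined scores (patients missing every
#'   category are excluded with a warning).
#' @export
combined_score <- function(raw) {
  cats <- setdiff(names(raw), "patient_id")
  if (nrow(raw) < 2) stopf("need at least 2 patients")
  ranks <- sapply(cats, function(cat) {
    x <- raw[[cat]]
    r <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    r[ok] <- rank(x[ok], ties.method = "average")
    r
  })
  ranks <- matrix(ranks, nrow = nrow(raw))
  n_present <- rowSums(!is.na(ranks))
  if (any(n_present == 0)) {
    warnf("excluding %d patient(s) with no clinical categories",
          sum(n_present == 0))
  }
  combined <- rowMeans(ranks, na.rm = TRUE)
  combined[n_present == 0] <- NA_real_
  out <- setNames(combined, raw$patient_id)
  out[!is.na(out)]
}

# Hurdle combined-mean fold change from a single (full-model) fit.
hurdle_fc <- function(y, design, test_cols) {
  if (all(y == 0)) return(0)
  X <- drop_aliased(as.matrix(design))
  test_cols <- intersect(test_cols, colnames(X))
  if (length(test_cols) == 0) return(0)
  ybin <- as.numeric(y > 0)
  fit <- logistic_deviance(X, ybin)
  xbar <- colMeans(X)
  x1 <- x0 <- xbar
  x1[test_cols] <- 1; x0[test_cols] <- 0
  pi1 <- plogis(sum(x1 * fit$coef)); pi0 <- plogis(sum(x0 * fit$coef))
  pos <- y > 0
  if (sum(pos) >= ncol(X) + 2) {
    Xp <- drop_aliased(X[pos, , drop = FALSE])
    lf <- lm.fit(Xp, y[pos])
    cc <- colnames(Xp)
    mu1 <- sum(x1[cc] * lf$coefficients)
    mu0 <- sum(x0[cc] * lf$coefficients)
  } else {
    mu1 <- mu0 <- mean(y[pos])
  }
  pi1 * mu1 - pi0 * mu0
}

#' Patient-level fold changes versus the control group
#'
#' Per gene, the hurdle combined-mean log2 fold change contrasting one
#' patient's cells with all control cells, covariate-adjusted where
#' estimable (aliased columns are dropped automatically).
#'
#' @param values genes x cells log2 expression (patient + control cells).
#' @param cells cell metadata aligned with columns (patient_id,
#'   detection_rate, ...).
#' @param patient patient id whose cells form the test group.
#' @param control_patients ids of the control individuals.
#' @param gene_list genes to compute fold changes for.
#' @param covariate_names covariates offered to the design.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
individual_fold_changes <- function(values, cells, patient, control_patients,
                                    gene_list,
                                    covariate_names = c("detection_rate")) {
  take <- cells$patient_id %in% c(patient, control_patients)
  cells <- cells[take, , drop = FALSE]
  values <- values[, take, drop = FALSE]
  group <- cells$patient_id == patient
  if (sum(group) < 3) stopf("patient %s has fewer than 3 cells", patient)
  if (sum(!group) == 0) stopf("empty control group")
  ds <- build_de_designs(group, cells, covariate_names)
  vapply(gene_list, function(g)
    hurdle_fc(values[g, ], ds$full, ".group"), numeric(1))
}

#' Per-gene Pearson correlation with the combined clinical score
#'
#' @param fc patients x genes matrix of individual-level fold changes.
#' @param combined named combined clinical scores.
#' @return data.frame (gene, r, p); zero-variance genes are excluded with a
#'   warning.
#' @export
gene_clinical_correlation <- function(fc, combined) {
  shared <- intersect(rownames(fc), names(combined))
  if (length(shared) < 3) stopf("need at least 3 patients with both values")
  fc <- fc[shared, , drop = FALSE]
  sc <- combined[shared]
  keep <- apply(fc, 2, function(x) var(x) > 0)
  if (any(!keep))
    warnf("excluding %d zero-variance gene(s) from correlation", sum(!keep))
  fc <- fc[, keep, drop = FALSE]
  res <- lapply(colnames(fc), function(g) {
    ct <- cor.test(fc[, g], sc, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fisher's method for combining p-values
#'
#' X = -2 sum(log p) referred to a chi-square with 2m degrees of freedom.
#'
#' @param p_values vector of p-values in (0, 1]; exact zeros are clamped to
#'   the smallest positive double with a warning.
#' @return combined meta p-value.
#' @export
fisher_meta <- function(p_values) {
  if (length(p_values) == 0) stopf("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warnf("clamping %d zero p-value(s)", sum(p_values == 0))
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p_values))
  pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Rank t-tests per clinical category: one subtype versus the rest
#'
#' Within each category, patient scores are rank-transformed (average ties)
#' and a Welch two-sample t-test compares the subtype's ranks with all other
#' subtypes'; BH correction is applied across the categories per subtype.
#'
#' @param clinical data.frame: patient_id plus category columns.
#' @param labels named subtype labels of the case patients.
#' @return data.frame (subtype, category, t, p, fdr); degenerate tests are
#'   reported NA with a flag.
#' @export
category_rank_ttests <- function(clinical, labels) {
  cats <- setdiff(names(clinical), "patient_id")
  pats <- intersect(clinical$patient_id, names(labels))
  clinical <- clinical[match(pats, clinical$patient_id), , drop = FALSE]
  lab <- labels[pats]
  out <- list()
  for (s in sort(unique(lab))) {
    rows <- lapply(cats, function(cat) {
      x <- clinical[[cat]]
      ok <- !is.na(x)
      r <- rep(NA_real_, length(x))
      r[ok] <- rank(x[ok], ties.method = "average")
      g1 <- r[ok & lab == s]; g0 <- r[ok & lab != s]
      if (length(g1) < 2 || length(g0) < 2 ||
          (var(g1) == 0 && var(g0) == 0))
        return(data.frame(subtype = s, category = cat, t = NA_real_,
                          p = NA_real_, flag = "degenerate",
                          stringsAsFactors = FALSE))
      tt <- t.test(g1, g0)
      data.frame(subtype = s, category = cat, t = unname(tt$statistic),
                 p = tt$p.value, flag = NA_character_,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- NA_real_
    ok <- !is.na(tab$p)
    tab$fdr[ok] <- bh_adjust(tab$p[ok])
    out[[length(out) + 1]] <- tab
  }
  do.call(rbind, out)
}

#' Hypergeometric over-representation test
#'
#' P(X >= overlap) with X ~ Hypergeometric(|universe|, |reference|,
#' |query|).
#'
#' @param query gene set of interest (subset of universe).
#' @param reference risk-gene set (subset of universe).
#' @param universe background gene ids.
#' @return list(overlap, p, fold) where fold is the observed/expected ratio.
#' @export
hypergeom_enrichment <- function(query, reference, universe) {
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% universe) || !all(reference %in% universe))
    stopf("query and reference must be subsets of the universe")
  ov <- length(intersect(query, reference))
  p <- phyper(ov - 1, length(reference),
              length(universe) - length(reference), length(query),
              lower.tail = FALSE)
  expected <- length(query) * length(reference) / length(universe)
  list(overlap = ov, p = p,
       fold = if (expected > 0) ov / expected else NA_real_)
}

#' Meta correlation of subtype-specific DEGs with clinical severity
#'
#' Per (subtype, cell type): cell types with fewer DEGs than the applicable
#' filter are reported NA; otherwise the DEGs' clinical correlation
#' p-values are combined by Fisher's method.
#'
#' @param deg_tables nested list \code{[[subtype]][[cell_type]]} of
#'   subtype-specific DE tables (thresholded).
#' @param fc_matrices list per cell type of patients x genes fold-change
#'   matrices (patient-level, vs controls).
#' @param combined named combined clinical scores.
#' @param params a \code{\link{clinical_params}}.
#' @return data.frame (subtype, cell_type, n_degs, meta_p, significant).
#' @export
meta_correlation_report <- function(deg_tables, fc_matrices, combined,
                                    params = clinical_params()) {
  out <- list()
  for (s in names(deg_tables)) {
    min_req <- if (s %in% params$small_filter_subtypes)
      params$min_degs_small else params$min_degs
    for (ct in names(deg_tables[[s]])) {
      degs <- unique(deg_tables[[s]][[ct]]$feature)
      degs <- intersect(degs, colnames(fc_matrices[[ct]]))
      meta_p <- NA_real_
      if (length(degs) >= min_req) {
        corr <- gene_clinical_correlation(
          fc_matrices[[ct]][, degs, drop = FALSE], combined)
        if (nrow(corr) > 0) meta_p <- fisher_meta(corr$p)
      }
      out[[length(out) + 1]] <- data.frame(
        subtype = s, cell_type = ct, n_degs = length(degs), meta_p = meta_p,
        significant = !is.na(meta_p) & meta_p < params$meta_alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
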