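## End-to-end orchestration of the two-level subtyping workflow:
## preprocess -> per-cell gene-set scoring -> per-cell-type patient profiles
## (genes; sets) -> fusion per modality -> final fusion -> model selection +
## clustering -> differential genes/sets -> subtype-specific intersection,
## unique/common, discordance -> clinical association + risk enrichment ->
## PLS-DA prediction. Every stage writes plain-text artifacts plus a
## manifest; identical (inputs, seed) reruns are byte-identical.

#' Pipeline configuration
#'
#' @param data_dir cohort directory (as written by \code{\link{write_cohort}}).
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed propagated to every stochastic stage.
#' @param n_hvg optional number of highly variable genes to keep.
#' @param hvg_exclude gene-id regexes removed before HVG ranking.
#' @param gsva_par,snf_par,thresholds,clinical_par stage parameter objects.
#' @param prediction_schemes which prediction schemes to run.
#' @param cv_repeats inner CV repeats for prediction (10 mirrors the
#'   original design; smaller values speed exploratory runs).
#' @param component_grid candidate PLS component numbers.
#' @param risk_genes optional path to a risk-gene list (one id per line).
#' @param min_prediction_features skip prediction for cell types with fewer
#'   subtype-specific DEG features than this.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(data_dir, out_dir, seed = 1L, n_hvg = NULL,
                            hvg_exclude = c("^MT-", "^RP[LS]"),
                            gsva_par = gsva_params(),
                            snf_par = snf_params(seed = seed),
                            thresholds = de_thresholds(),
                            clinical_par = clinical_params(),
                            prediction_schemes = c("random_cells",
                                                   "leave_patient_out"),
                            cv_repeats = 10L,
                            component_grid = 1:5,
                            risk_genes = NULL,
                            min_prediction_features = 3L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full subtyping pipeline
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with the main in-memory results: subtype
#'   assignment, fused matrices, DE tables, clinical and prediction reports,
#'   and the manifest. Artifacts are written under \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  done <- function(stage, status = "complete")
    manifest$stages[[stage]] <<- status

  cohort <- read_cohort(config$data_dir)
  done("read")

  cell_types <- names(cohort$counts)
  expr <- list()
  for (ct in cell_types) {
    cdf <- cohort$cells[cohort$cells$cell_type == ct, , drop = FALSE]
    e <- normalize_log(cohort$counts[[ct]], cdf, cohort$patients)
    if (!is.null(config$n_hvg))
      e <- select_hvg(e, config$n_hvg, config$hvg_exclude)
    expr[[ct]] <- e
  }
  done("preprocess")

  scores <- lapply(expr, gsva_scores, sets = cohort$sets,
                   params = config$gsva_par)
  done("gsva")

  case_ids <- cohort$patients$patient_id[cohort$patients$diagnosis == "case"]
  case_profiles <- function(obj) {
    keep <- obj$cells$patient_id %in% case_ids
    pr <- patient_mean_profiles(
      structure(list(values = obj$values[, keep, drop = FALSE],
                     cells = obj$cells[keep, , drop = FALSE]),
                class = class(obj)))
    pr[case_ids[case_ids %in% rownames(pr)], , drop = FALSE]
  }
  gene_profiles <- lapply(expr, case_profiles)
  set_profiles <- lapply(scores, case_profiles)
  done("profiles")

  fused_genes <- fuse_views(gene_profiles, config$snf_par)
  fused_sets <- fuse_views(set_profiles, config$snf_par)
  done("fusion_modality")
  fused_final <- snf_fuse(list(genes = fused_genes, sets = fused_sets),
                          config$snf_par)
  done("fusion_final")

  assign_genes <- subtype_patients(fused_genes, config$snf_par)
  assign_sets <- subtype_patients(fused_sets, config$snf_par)
  assignment <- subtype_patients(fused_final, config$snf_par)
  labels <- assignment$labels
  done("clustering")

  write_tsv(data.frame(patient_id = names(labels), subtype = labels),
            file.path(out, "labels.tsv"))
  for (nm in c("fused_genes", "fused_sets", "fused_final")) {
    m <- get(nm)
    write_tsv(data.frame(patient_id = rownames(m), round(m, 10),
                         check.names = FALSE),
              file.path(out, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(
    list(k = assignment$k,
         silhouette_final = assignment$silhouette,
         silhouette_genes = assign_genes$silhouette,
         silhouette_sets = assign_sets$silhouette,
         k_genes = assign_genes$k, k_sets = assign_sets$k,
         selection = assignment$selection$diagnostics),
    file.path(out, "clustering_diagnostics.json"),
    auto_unbox = TRUE, digits = NA)

  ## differential expression per (cell type, subtype, comparison)
  de <- run_de_stage(expr, scores, labels, cohort$patients,
                     config$thresholds)
  done("diffexpr")
  write_tsv(de$genes_kept, file.path(out, "de_genes.tsv"))
  write_tsv(de$sets_kept, file.path(out, "de_sets.tsv"))
  write_tsv(de$specific_genes, file.path(out, "subtype_specific_genes.tsv"))
  write_tsv(de$specific_sets, file.path(out, "subtype_specific_sets.tsv"))
  write_tsv(de$discordant, file.path(out, "discordant_events.tsv"))

  ## clinical association
  clin_results <- NULL
  if (!is.null(cohort$clinical)) {
    clin_results <- run_clinical_stage(expr, de, cohort, labels,
                                       config$clinical_par,
                                       risk_genes = config$risk_genes)
    write_tsv(clin_results$meta, file.path(out, "clinical_meta.tsv"))
    write_tsv(clin_results$ttests, file.path(out, "clinical_ttests.tsv"))
    if (!is.null(clin_results$risk))
      write_tsv(clin_results$risk, file.path(out, "risk_enrichment.tsv"))
    done("clinical")
  } else {
    warnf("no clinical table found; clinical stage skipped")
    done("clinical", "skipped")
  }

  ## prediction
  pred_reports <- list()
  subtype_of_patient <- setNames(labels, names(labels))
  for (ct in cell_types) {
    feats <- unique(de$specific_genes$feature[de$specific_genes$cell_type == ct])
    if (length(feats) < config$min_prediction_features) next
    e <- expr[[ct]]
    keep <- e$cells$patient_id %in% case_ids
    vals <- e$values[feats, keep, drop = FALSE]
    pats <- e$cells$patient_id[keep]
    for (scheme in config$prediction_schemes) {
      par <- prediction_params(scheme = scheme, seed = config$seed,
                               cv_repeats = config$cv_repeats,
                               component_grid = config$component_grid)
      rep_ <- tryCatch(run_prediction(vals, pats, subtype_of_patient, par),
                       error = function(e) NULL)
      if (!is.null(rep_))
        pred_reports[[paste(ct, scheme, sep = ".")]] <-
          rep_[c("scheme", "n_components", "micro_f1", "macro_f1",
                 "weighted_f1", "accuracy")]
    }
  }
  jsonlite::write_json(pred_reports, file.path(out, "prediction.json"),
                       auto_unbox = TRUE, digits = NA)
  done("prediction")

  jsonlite::write_json(
    list(seed = config$seed, stages = manifest$stages,
         parameters = list(
           K = config$snf_par$K, T = config$snf_par$T,
           mu = config$snf_par$mu,
           gsva_min_size = config$gsva_par$min_size,
           logfc_min = config$thresholds$logfc_min,
           fdr_max = config$thresholds$fdr_max)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(assignment = assignment, fused_final = fused_final,
                 fused_genes = fused_genes, fused_sets = fused_sets,
                 assign_genes = assign_genes, assign_sets = assign_sets,
                 de = de, clinical = clin_results,
                 prediction = pred_reports, manifest = manifest,
                 expr = expr, scores = scores))
}

# DE stage over every (cell type, subtype): both comparisons for genes
# (hurdle) and set scores (moderated), subtype-specific intersection,
# unique/common partition and discordance screen.
run_de_stage <- function(expr, scores, labels, patients, thresholds) {
  subs <- sort(unique(labels))
  genes_kept <- list(); sets_kept <- list()
  specific_genes <- list(); specific_sets <- list()
  discordant <- list()
  for (ct in names(expr)) {
    e <- expr[[ct]]
    sc <- scores[[ct]]
    ct_specific_g <- list(); ct_specific_s <- list()
    fc_ctrl_g <- list()
    for (s in subs) {
      res <- de_both_comparisons(e$values, e$cells, labels, s, ct,
                                 thresholds, "hurdle", "gene")
      res_s <- de_both_comparisons(sc$values, sc$cells, labels, s, ct,
                                   thresholds, "moderated", "gene_set")
      genes_kept[[paste(ct, s)]] <- rbind(res$vs_subtypes, res$vs_controls)
      sets_kept[[paste(ct, s)]] <- rbind(res_s$vs_subtypes, res_s$vs_controls)
      spg <- subtype_specific(res$vs_subtypes, res$vs_controls)
      sps <- subtype_specific(res_s$vs_subtypes, res_s$vs_controls)
      ct_specific_g[[as.character(s)]] <- spg
      ct_specific_s[[as.character(s)]] <- sps
      full_ctrl <- attr(res$vs_controls, "full")
      fc_ctrl_g[[as.character(s)]] <- full_ctrl
    }
    specific_genes[[ct]] <- do.call(rbind, ct_specific_g)
    specific_sets[[ct]] <- do.call(rbind, ct_specific_s)
    part <- partition_unique_common(ct_specific_g)
    if (length(part$common)) {
      fc_tab <- do.call(rbind, lapply(names(fc_ctrl_g), function(s) {
        t <- fc_ctrl_g[[s]]
        t <- t[t$feature %in% part$common, c("feature", "log2fc"), drop = FALSE]
        if (nrow(t)) data.frame(feature = t$feature, subtype = s,
                                log2fc = t$log2fc, cell_type = ct,
                                stringsAsFactors = FALSE)
      }))
      discordant[[ct]] <- discordant_events(part$common, fc_tab)
    }
  }
  empty_de <- data.frame(feature = character(), feature_kind = character(),
                         cell_type = character(), subtype = integer(),
                         comparison = character(), log2fc = numeric(),
                         p = numeric(), fdr = numeric(),
                         direction = character(), stringsAsFactors = FALSE)
  bind <- function(lst) {
    lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
    if (length(lst)) { o <- do.call(rbind, lst); rownames(o) <- NULL; o }
    else empty_de
  }
  list(genes_kept = bind(genes_kept), sets_kept = bind(sets_kept),
       specific_genes = bind(specific_genes),
       specific_sets = bind(specific_sets),
       discordant = if (length(discordant)) {
         o <- do.call(rbind, discordant); rownames(o) <- NULL; o
       } else data.frame(feature = character(), cell_type = character(),
                         subtype = character(), stringsAsFactors = FALSE))
}

de_both_comparisons <- function(values, cells, labels, s, ct, thresholds,
                                method, kind) {
  case_cells <- cells$patient_id %in% names(labels)
  in_sub <- cells$patient_id %in% names(labels)[labels == s]
  ## vs other subtypes: case cells only
  v1 <- de_features(values[, case_cells, drop = FALSE],
                    in_sub[case_cells],
                    cells[case_cells, , drop = FALSE],
                    cell_type = ct, subtype = s,
                    comparison = "vs_other_subtypes",
                    thresholds = thresholds, method = method,
                    feature_kind = kind)
  ## vs controls: this subtype's cells plus control cells
  ctrl <- cells$diagnosis == "control"
  take <- in_sub | ctrl
  v2 <- de_features(values[, take, drop = FALSE], in_sub[take],
                    cells[take, , drop = FALSE],
                    cell_type = ct, subtype = s,
                    comparison = "vs_controls",
                    thresholds = thresholds, method = method,
                    feature_kind = kind)
  list(vs_subtypes = v1, vs_controls = v2)
}

# Clinical stage: combined score, patient-level fold changes over each cell
# type's subtype-specific DEGs, Fisher meta correlation, per-category rank
# t-tests, optional risk-gene enrichment.
run_clinical_stage <- function(expr, de, cohort, labels, clinical_par,
                               risk_genes = NULL) {
  combined <- combined_score(cohort$clinical)
  control_ids <- cohort$patients$patient_id[cohort$patients$diagnosis == "control"]
  deg_tables <- list()
  for (s in sort(unique(labels))) {
    deg_tables[[as.character(s)]] <- list()
    for (ct in names(expr)) {
      t <- de$specific_genes
      deg_tables[[as.character(s)]][[ct]] <-
        t[t$subtype == s & t$cell_type == ct, , drop = FALSE]
    }
  }
  fc_matrices <- list()
  for (ct in names(expr)) {
    genes <- unique(de$specific_genes$feature[de$specific_genes$cell_type == ct])
    if (length(genes) == 0) {
      fc_matrices[[ct]] <- matrix(numeric(0), nrow = length(names(labels)),
                                  ncol = 0,
                                  dimnames = list(names(labels), NULL))
      next
    }
    e <- expr[[ct]]
    fc <- t(vapply(names(labels), function(p)
      individual_fold_changes(e$values, e$cells, p, control_ids, genes),
      numeric(length(genes))))
    colnames(fc) <- genes
    fc_matrices[[ct]] <- fc
  }
  meta <- meta_correlation_report(deg_tables, fc_matrices, combined,
                                  clinical_par)
  ttests <- category_rank_ttests(cohort$clinical, labels)
  risk <- NULL
  if (!is.null(risk_genes)) {
    ref <- intersect(read_gene_list(risk_genes), cohort$gene_ids)
    rows <- list()
    for (s in names(deg_tables)) for (ct in names(deg_tables[[s]])) {
      q <- unique(deg_tables[[s]][[ct]]$feature)
      if (length(q) < clinical_par$min_degs) next
      h <- hypergeom_enrichment(q, ref, cohort$gene_ids)
      rows[[length(rows) + 1]] <- data.frame(
        subtype = s, cell_type = ct, n_degs = length(q),
        overlap = h$overlap, p = h$p, fold = h$fold,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      risk <- do.call(rbind, rows)
      risk$fdr <- NA_real_
      for (s in unique(risk$subtype)) {
        idx <- risk$subtype == s
        risk$fdr[idx] <- bh_adjust(risk$p[idx])
      }
    }
  }
  list(combined = combined, meta = meta, ttests = ttests, risk = risk,
       fc_matrices = fc_matrices)
}
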