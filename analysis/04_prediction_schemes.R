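#!/usr/bin/env Rscript
# Train PLS-DA subtype classifiers under the three splitting schemes
# (stratified 7:3 cells; leave one patient per subtype out; patient-level
# mean profiles with repeated holdout) for every cell type with enough
# subtype-specific DEG features, and tabulate micro/macro/weighted F1.

suppressPackageStartupMessages(library(snfsubtypes))
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))

cohort <- read_cohort("data/cohort")
labels_tab <- read_tsv("results/pipeline/labels.tsv")
subtype_of_patient <- setNames(labels_tab$subtype, labels_tab$patient_id)
spec <- read_tsv("results/pipeline/subtype_specific_genes.tsv")

rows <- list()
for (ct in names(cohort$counts)) {
  feats <- unique(spec$feature[spec$cell_type == ct])
  if (length(feats) < 3) next
  cdf <- cohort$cells[cohort$cells$cell_type == ct, ]
  e <- normalize_log(cohort$counts[[ct]], cdf, cohort$patients)
  keep <- e$cells$patient_id %in% names(subtype_of_patient)
  vals <- e$values[feats, keep]
  pats <- e$cells$patient_id[keep]
  for (scheme in c("random_cells", "leave_patient_out", "patient_level")) {
    par <- prediction_params(scheme, seed = seed,
                             outer_repeats = if (scheme == "patient_level") 10L else 10L)
    rep_ <- run_prediction(vals, pats, subtype_of_patient, par)
    rows[[paste(ct, scheme)]] <- data.frame(
      cell_type = ct, scheme = scheme, n_features = length(feats),
      n_components = rep_$n_components,
      micro_f1 = round(rep_$micro_f1, 3), macro_f1 = round(rep_$macro_f1, 3),
      weighted_f1 = round(rep_$weighted_f1, 3),
      accuracy = round(if (scheme == "patient_level") rep_$mean_accuracy
                       else rep_$accuracy, 3))
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
dir.create("results", showWarnings = FALSE)
write_tsv(tab, "results/prediction_metrics.tsv")
print(tab)
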