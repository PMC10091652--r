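#!/usr/bin/env Rscript
# Derive subtypes independently on the pseudo-bulk matrix with the same
# GSVA + SNF pipeline (single cell-type special case) and relate the two
# subtype systems through Pearson correlation of their per-subtype fold
# changes. Writes the correspondence matrices to results/correspondence/.

suppressPackageStartupMessages(library(snfsubtypes))
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))

cohort <- read_cohort("data/cohort")
truth <- unlist(cohort$truth$subtype_of_patient)
bulk_tab <- read_tsv("data/cohort/bulk.tsv")
bulk <- as.matrix(bulk_tab[, -1])
rownames(bulk) <- bulk_tab$patient_id

labels <- read_tsv("results/pipeline/labels.tsv")
sn_labels <- setNames(labels$subtype, labels$patient_id)

## bulk subtypes from scratch (cases only, like the single-nucleus run)
bs <- bulk_subtypes(bulk[names(truth), ], cohort$sets,
                    gsva_params(min_size = 5), snf_params(seed = seed))
cat(sprintf("bulk subtyping: k = %d, silhouette = %.2f, ARI vs planted = %.2f\n",
            bs$k, bs$silhouette,
            adjusted_rand_index(bs$labels, truth[names(bs$labels)])))

## fold-change signatures: single-nucleus (combined across cell types) vs bulk
all_vals <- list(); all_pats <- list()
for (ct in names(cohort$counts)) {
  cdf <- cohort$cells[cohort$cells$cell_type == ct, ]
  e <- normalize_log(cohort$counts[[ct]], cdf, cohort$patients)
  keep <- e$cells$patient_id %in% names(sn_labels)
  all_vals[[ct]] <- e$values[, keep]
  all_pats[[ct]] <- e$cells$patient_id[keep]
}
fc_sn <- subtype_fold_changes(do.call(cbind, all_vals),
                              unlist(all_pats, use.names = FALSE), sn_labels)
fc_bulk <- subtype_fold_changes(t(bulk[names(bs$labels), ]),
                                names(bs$labels), bs$labels)
cm <- correspondence_matrix(fc_sn, fc_bulk)

dir.create("results/correspondence", recursive = TRUE, showWarnings = FALSE)
write_tsv(data.frame(sn_subtype = rownames(cm$r), round(cm$r, 6),
                     check.names = FALSE),
          "results/correspondence/correlation.tsv")
write_tsv(data.frame(sn_subtype = rownames(cm$p), signif(cm$p, 6),
                     check.names = FALSE),
          "results/correspondence/p_values.tsv")
cat("correspondence (rows = single-nucleus subtypes, cols = bulk subtypes):\n")
print(round(cm$r, 3))
cat(sprintf("row-wise best match: %s\n",
            paste(colnames(cm$r)[apply(cm$r, 1, which.max)], collapse = " ")))
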