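#!/usr/bin/env Rscript
# Simulate the default synthetic cohort (15 cases in planted subtypes of
# 6/4/5, 16 controls, 3 cell types, 500 genes, 50 gene sets) plus the
# matched pseudo-bulk matrix, and write everything under data/cohort/.
# Later analysis steps read these files; re-running with the same seed
# reproduces them byte for byte.

suppressPackageStartupMessages(library(snfsubtypes))
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
dir.create("data", showWarnings = FALSE)
write_cohort(cohort, "data/cohort")

bulk <- simulate_bulk(cfg, cohort$truth)
write_tsv(data.frame(patient_id = rownames(bulk), round(bulk, 6),
                     check.names = FALSE),
          "data/cohort/bulk.tsv")

cat(sprintf("cohort: %d cells, %d genes, %d gene sets, %d patients\n",
            nrow(cohort$cells), length(cohort$gene_ids),
            length(cohort$sets), nrow(cohort$patients)))
cat(sprintf("planted subtypes: %s\n",
            paste(table(cohort$truth$subtype_of_patient), collapse = "/")))
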