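test_that("combined score is the mean of within-category ranks", {
  raw <- data.frame(patient_id = c("a", "b", "c"),
                    A = c(1, 2, 3), C = c(3, 2, 1))
  expect_equal(unname(combined_score(raw)), c(2, 2, 2))
  # one category: combined equals that category's ranks
  one <- data.frame(patient_id = c("a", "b", "c"), A = c(5, 1, 3))
  expect_equal(combined_score(one), c(a = 3, b = 1, c = 2))
  # all tied: every patient gets (n + 1) / 2
  tied <- data.frame(patient_id = c("a", "b", "c"), A = c(2, 2, 2))
  expect_equal(unname(combined_score(tied)), rep(2, 3))
  # invariant under strictly monotone transforms of a category
  raw2 <- raw; raw2$A <- exp(raw$A); raw2$C <- raw$C^3
  expect_equal(combined_score(raw2), combined_score(raw))
  # patients with no categories at all are excluded with a warning
  miss <- data.frame(patient_id = c("a", "b"), A = c(1, NA), C = c(2, NA))
  expect_warning(cs <- combined_score(miss), "no clinical categories")
  expect_identical(names(cs), "a")
})

test_that("Fisher's method matches the chi-square oracle", {
  # single p returns exactly that p
  for (p in c(0.5, 0.031, 0.9)) expect_equal(fisher_meta(p), p)
  expect_equal(fisher_meta(c(1, 1, 1)), 1)
  # two p = 0.05: X = -4 ln 0.05 = 11.983; survival of chi-square df 4
  expect_equal(fisher_meta(c(0.05, 0.05)),
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  X <- -4 * log(0.05)   # chi-square df 4 survival: exp(-X/2) * (1 + X/2)
  expect_equal(fisher_meta(c(0.05, 0.05)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-10)
  # monotone and exchangeable
  expect_lt(fisher_meta(c(0.01, 0.2)), fisher_meta(c(0.05, 0.2)))
  expect_equal(fisher_meta(c(0.3, 0.02)), fisher_meta(c(0.02, 0.3)))
  expect_error(fisher_meta(numeric(0)), "empty")
  expect_error(fisher_meta(c(0.5, 1.2)), "lie in")
  expect_warning(p0 <- fisher_meta(c(0, 0.5)), "clamping")
  expect_lt(p0, 1e-100)
})

test_that("per-gene clinical correlation handles exact and degenerate cases", {
  fc <- cbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), g3 = rep(2, 4))
  rownames(fc) <- paste0("p", 1:4)
  score <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  expect_warning(out <- gene_clinical_correlation(fc, score), "zero-variance")
  expect_equal(out$r[out$gene == "g1"], 1)
  expect_equal(out$r[out$gene == "g2"], -1)
  expect_lt(out$p[out$gene == "g2"], 0.01)
  expect_false("g3" %in% out$gene)
  expect_error(gene_clinical_correlation(fc[1:2, ], score[1:2]), "3 patients")
})

test_that("category rank t-tests flag the separated category most strongly", {
  set.seed(5)
  labels <- setNames(rep(1:3, c(6, 4, 5)), sprintf("P%02d", 1:15))
  clin <- data.frame(patient_id = names(labels),
                     A = rnorm(15), B_verbal = rnorm(15),
                     B_nonverbal = rnorm(15), C = rnorm(15), D = rnorm(15))
  clin$C[labels == 1] <- clin$C[labels == 1] - 10   # subtype 1 lowest C ranks
  out <- category_rank_ttests(clin, labels)
  s1 <- out[out$subtype == 1, ]
  expect_equal(s1$category[which.min(s1$p)], "C")
  expect_lt(s1$t[s1$category == "C"], 0)
  expect_true(all(out$fdr >= out$p, na.rm = TRUE))
})

test_that("rank t-test p-values are uniform under a permutation null", {
  set.seed(6)
  labels <- setNames(rep(1:3, c(6, 4, 5)), sprintf("P%02d", 1:15))
  pv <- replicate(300, {
    clin <- data.frame(patient_id = names(labels), A = rnorm(15))
    out <- category_rank_ttests(clin, sample(labels))
    out$p[out$subtype == 1]
  })
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.09)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  uni <- paste0("g", 1:10)
  ref <- uni[1:4]
  qry <- uni[c(1, 2, 3, 5, 6)]
  h <- hypergeom_enrichment(qry, ref, uni)
  expect_equal(h$overlap, 3)
  expect_equal(h$p, 66 / 252, tolerance = 1e-12)
  expect_equal(h$p, oracle_hypergeom(10, 4, 5, 3), tolerance = 1e-12)
  # overlap 0 has p = 1; reference = universe forces full overlap, p = 1
  expect_equal(hypergeom_enrichment(uni[5:6], uni[1:2], uni)$p, 1)
  expect_equal(hypergeom_enrichment(uni[1:3], uni, uni)$p, 1)
  expect_error(hypergeom_enrichment("x", ref, uni), "subsets")
  expect_error(hypergeom_enrichment("g1", "g1", character(0)), "empty")
  # sweep every configuration on a small universe against enumeration
  for (U in c(6, 9, 12)) {
    uni <- paste0("g", seq_len(U))
    set.seed(U)
    for (i in 1:10) {
      ref <- sample(uni, sample(U - 1, 1))
      qry <- sample(uni, sample(U - 1, 1))
      ov <- length(intersect(ref, qry))
      expect_equal(hypergeom_enrichment(qry, ref, uni)$p,
                   oracle_hypergeom(U, length(ref), length(qry), ov),
                   tolerance = 1e-12)
    }
  }
})

test_that("meta correlation report applies the DEG-count filters", {
  deg <- function(n) data.frame(feature = paste0("g", seq_len(n)),
                                stringsAsFactors = FALSE)
  deg_tables <- list(`1` = list(ct1 = deg(9), ct2 = deg(12)))
  set.seed(3)
  fc <- matrix(rnorm(15 * 12), 15, 12,
               dimnames = list(sprintf("P%02d", 1:15), paste0("g", 1:12)))
  fcs <- list(ct1 = fc, ct2 = fc)
  combined <- setNames(rnorm(15), rownames(fc))
  rep <- meta_correlation_report(deg_tables, fcs, combined,
                                 clinical_params(min_degs = 10))
  expect_true(is.na(rep$meta_p[rep$cell_type == "ct1"]))   # 9 < 10 -> NA
  expect_false(is.na(rep$meta_p[rep$cell_type == "ct2"]))
  # the relaxed filter admits the small table when configured
  rep2 <- meta_correlation_report(deg_tables, fcs, combined,
                                  clinical_params(min_degs = 10,
                                                  min_degs_small = 5,
                                                  small_filter_subtypes = "1"))
  expect_false(any(is.na(rep2$meta_p)))
})

test_that("clinical linkage produces a detectable meta-correlation signal", {
  cfg <- sim_config(seed = 31, cell_types = "CT1",
                    cells_per_patient_per_type = 60L, n_genes = 200L,
                    patient_effect_range = c(0.5, 1.5),
                    clinical_linkage = 15, clinical_noise_sd = 0.5)
  co <- simulate_cohort(cfg)
  e <- normalize_log(co$counts[["CT1"]], co$cells, co$patients)
  truth <- co$truth$subtype_of_patient
  combined <- combined_score(co$clinical)
  controls <- co$patients$patient_id[co$patients$diagnosis == "control"]
  genes <- co$truth$de_features[["1|CT1"]]$gene
  fc <- t(vapply(names(truth), function(p)
    individual_fold_changes(e$values, e$cells, p, controls, genes),
    numeric(length(genes))))
  corr <- gene_clinical_correlation(fc, combined)
  expect_lt(fisher_meta(corr$p), 0.1)
})

test_that("patient-level fold changes are near zero for null patients", {
  cfg <- sim_config(seed = 33, cell_types = "CT1", de_log2fc = 0,
                    cells_per_patient_per_type = 60L, n_genes = 100L)
  co <- simulate_cohort(cfg)
  e <- normalize_log(co$counts[["CT1"]], co$cells, co$patients)
  controls <- co$patients$patient_id[co$patients$diagnosis == "control"]
  genes <- co$gene_ids[1:20]
  fc <- individual_fold_changes(e$values, e$cells, "P01", controls, genes)
  expect_length(fc, 20)
  expect_lt(mean(abs(fc)), 0.25)
  expect_error(individual_fold_changes(e$values, e$cells, "P01",
                                       character(0), genes), "control")
})

test_that("zero clinical linkage gives no systematic meta-correlation signal", {
  meta_ps <- vapply(1:10, function(i) {
    cfg <- small_config(seed = 400 + i, cell_types = "CT1",
                        n_genes = 80L, de_genes_per_subtype_per_type = 10L,
                        clinical_linkage = 0)
    co <- simulate_cohort(cfg)
    e <- normalize_log(co$counts[["CT1"]], co$cells, co$patients)
    truth <- co$truth$subtype_of_patient
    combined <- combined_score(co$clinical)
    controls <- co$patients$patient_id[co$patients$diagnosis == "control"]
    genes <- co$truth$de_features[["1|CT1"]]$gene
    fc <- t(vapply(names(truth), function(p)
      individual_fold_changes(e$values, e$cells, p, controls, genes),
      numeric(length(genes))))
    corr <- suppressWarnings(gene_clinical_correlation(fc, combined))
    fisher_meta(corr$p)
  }, numeric(1))
  expect_lte(sum(meta_ps < 0.1), 3)
})
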