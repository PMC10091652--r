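sim_cells <- function(n = 120, p_zero = 0.3, effect = 0, seed = 1) {
  set.seed(seed)
  group <- rep(c(0, 1), each = n / 2)
  y <- rnorm(n, mean = 2 + effect * group, sd = 1)
  y[runif(n) < p_zero] <- 0
  y <- pmax(y, 0)
  list(y = y, group = group,
       design_full = cbind(`(Intercept)` = 1, .group = group),
       design_reduced = cbind(`(Intercept)` = rep(1, n)))
}

test_that("identical nested designs give a null LRT", {
  d <- sim_cells()
  res <- hurdle_lrt(d$y, d$design_reduced, d$design_reduced)
  expect_equal(res$p, 1)
  expect_equal(res$stat, 0, tolerance = 1e-8)
})

test_that("all-zero features are flagged with p = 1 and zero effect", {
  d <- sim_cells()
  res <- hurdle_lrt(rep(0, length(d$y)), d$design_full, d$design_reduced)
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)
  expect_equal(res$flag, "all_zero")
})

test_that("continuous part reduces to the classical Gaussian LRT when all cells express", {
  set.seed(3)
  n <- 80
  group <- rep(c(0, 1), each = n / 2)
  y <- rnorm(n, 5 + 0.4 * group)     # strictly positive, no zeros
  stopifnot(all(y > 0))
  full <- cbind(`(Intercept)` = 1, .group = group)
  red <- cbind(`(Intercept)` = rep(1, n))
  res <- hurdle_lrt(y, full, red)
  # discrete part is degenerate (all detected) so only the continuous LRT
  # contributes; compare at 1 df against the textbook statistic
  p_cont <- pchisq(res$stat_cont, df = 1, lower.tail = FALSE)
  expect_equal(p_cont, oracle_gaussian_lrt(y, group), tolerance = 1e-8)
})

test_that("hurdle p-values are calibrated and near-uniform under the null", {
  set.seed(10)
  reps <- 400
  pv <- vapply(seq_len(reps), function(i) {
    d <- sim_cells(n = 200, seed = 1000 + i)
    hurdle_lrt(d$y, d$design_full, d$design_reduced)$p
  }, numeric(1))
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.08)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("hurdle fold change tracks a planted shift", {
  d <- sim_cells(n = 400, effect = 1, seed = 4)
  res <- hurdle_lrt(d$y, d$design_full, d$design_reduced)
  expect_lt(res$p, 1e-4)
  expect_gt(res$log2fc, 0.4)
})

test_that("de_features applies both the fold-change and FDR gates", {
  set.seed(6)
  n <- 60
  group <- rep(c(FALSE, TRUE), each = n / 2)
  covars <- data.frame(detection_rate = runif(n, 0.4, 0.6))
  values <- rbind(
    big = 2 + 1.5 * group + rnorm(n, sd = 0.3),     # passes both gates
    tiny = 2 + 0.05 * group + rnorm(n, sd = 0.02),  # significant, tiny fc
    noisy = 2 + rnorm(n, sd = 1))                   # neither
  out <- de_features(values, group, covars, thresholds = de_thresholds())
  expect_true("big" %in% out$feature)
  expect_false("tiny" %in% out$feature)   # |fc| < 0.14 despite small p
  full <- attr(out, "full")
  expect_equal(nrow(full), 3)
  expect_true(all(full$fdr >= full$p))
  expect_true(all(out$direction == ifelse(out$log2fc >= 0, "up", "down")))
  expect_error(de_features(values, c(TRUE, rep(FALSE, n - 1)), covars),
               "at least 3 cells")
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(7)
  p <- runif(30)
  fdr <- p.adjust(p, "BH")
  o <- order(p)
  expect_true(all(diff(fdr[o]) >= -1e-12))
  expect_true(all(fdr >= p))
})

test_that("planted DE genes are recovered with high sensitivity and low FDP", {
  cfg <- sim_config(seed = 21, cell_types = "CT1",
                    cells_per_patient_per_type = 100L)
  co <- simulate_cohort(cfg)
  e <- normalize_log(co$counts[["CT1"]], co$cells, co$patients)
  truth <- co$truth$subtype_of_patient
  s1 <- names(truth)[truth == 1]
  # subtype 1 versus controls: a clean planted contrast
  take <- e$cells$patient_id %in% s1 | e$cells$diagnosis == "control"
  vals <- e$values[, take]
  cells <- e$cells[take, ]
  expect_gt(sum(take), 2000)
  out <- de_features(vals, cells$patient_id %in% s1, cells,
                     comparison = "vs_controls",
                     thresholds = de_thresholds())
  planted <- co$truth$de_features[["1|CT1"]]$gene
  sens <- mean(planted %in% out$feature)
  fdp <- if (nrow(out)) mean(!out$feature %in% planted) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("moderated t matches limma's empirical Bayes chain", {
  skip_if_not_installed("limma")
  set.seed(8)
  Y <- matrix(rnorm(10 * 8, sd = rep(runif(10, 0.5, 2), each = 8)), 10, 8,
              byrow = FALSE)
  rownames(Y) <- paste0("f", 1:10)
  grp <- rep(c(0, 1), each = 4)
  X <- cbind(`(Intercept)` = 1, .group = grp)
  mine <- moderated_lm(Y, X, coef = ".group")
  fit <- limma::lmFit(Y, X)
  eb <- limma::eBayes(fit)
  expect_lt(max(abs(mine$t - eb$t[, ".group"])), 1e-8)
  expect_lt(max(abs(mine$p - eb$p.value[, ".group"])), 1e-8)
  expect_equal(attr(mine, "d0"), eb$df.prior, tolerance = 1e-6)
})

test_that("prior-df limits of the moderated model hold exactly", {
  set.seed(9)
  Y <- matrix(rnorm(6 * 10), 6, 10)
  rownames(Y) <- paste0("f", 1:6)
  X <- cbind(`(Intercept)` = 1, .group = rep(c(0, 1), each = 5))
  inf_fit <- moderated_lm(Y, X, d0_override = Inf)
  expect_equal(length(unique(round(inf_fit$s2_post, 12))), 1)
  zero_fit <- moderated_lm(Y, X, d0_override = 0)
  # d0 = 0: moderated t equals the ordinary t-statistic
  ols <- lm.fit(X, t(Y))
  s2 <- colSums(as.matrix(ols$residuals)^2) / (10 - 2)
  v <- chol2inv(chol(crossprod(X)))[2, 2]
  t_ord <- t(as.matrix(ols$coefficients))[, ".group"] / sqrt(s2 * v)
  expect_equal(unname(zero_fit$t), unname(t_ord), tolerance = 1e-10)
})

test_that("subtype-specific features are the intersection of the comparisons", {
  tab <- function(f, fc = 1) data.frame(
    feature = f, feature_kind = "gene", cell_type = "t", subtype = 1,
    comparison = "vs_other_subtypes", log2fc = fc, p = 0.001, fdr = 0.01,
    direction = ifelse(fc >= 0, "up", "down"), stringsAsFactors = FALSE)
  a <- tab(c("g1", "g2", "g3"), c(1, -1, 2))
  b <- tab(c("g2", "g4"))
  out <- subtype_specific(a, b)
  expect_identical(out$feature, "g2")
  expect_equal(out$log2fc, -1)             # effect from vs-subtypes side
  expect_equal(nrow(subtype_specific(a, a[0, , drop = FALSE])), 0)
  expect_equal(subtype_specific(a, a), a, ignore_attr = TRUE)   # idempotent
})

test_that("unique/common partition follows set algebra", {
  mk <- function(f) data.frame(feature = f, log2fc = seq_along(f),
                               stringsAsFactors = FALSE)
  tabs <- list(`1` = mk(c("A", "B")), `2` = mk(c("B", "C")), `3` = mk("B"))
  part <- partition_unique_common(tabs)
  expect_setequal(part$unique$feature, c("A", "C"))
  expect_equal(part$unique$subtype[part$unique$feature == "A"], "1")
  expect_identical(part$common, "B")
  # disjoint tables: all unique, none common
  p2 <- partition_unique_common(list(`1` = mk("X"), `2` = mk("Y")))
  expect_setequal(p2$unique$feature, c("X", "Y"))
  expect_length(p2$common, 0)
  # identical tables: all common, none unique
  p3 <- partition_unique_common(list(`1` = mk(c("X", "Y")),
                                     `2` = mk(c("X", "Y"))))
  expect_null(p3$unique)
  expect_setequal(p3$common, c("X", "Y"))
})

test_that("discordant events are attributed to the minority-sign subtype", {
  fc <- data.frame(feature = rep(c("g1", "g2", "g3"), each = 3),
                   subtype = rep(c("1", "2", "3"), 3),
                   log2fc = c(1, 2, 1,      # concordant
                              1, 1, -2,     # subtype 3 discordant
                              -1, 2, 1),    # subtype 1 discordant
                   cell_type = "t", stringsAsFactors = FALSE)
  ev <- discordant_events(c("g1", "g2", "g3"), fc)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$subtype[ev$feature == "g2"], "3")
  expect_equal(ev$subtype[ev$feature == "g3"], "1")
  # zero fold changes cast no vote
  fc0 <- data.frame(feature = "g", subtype = c("1", "2", "3"),
                    log2fc = c(0, 1, 1), cell_type = "t")
  expect_equal(nrow(discordant_events("g", fc0)), 0)
})

test_that("a null cohort yields few false DE calls over the gene universe", {
  cfg <- sim_config(seed = 27, cell_types = "CT1", de_log2fc = 0,
                    clinical_linkage = 0, cells_per_patient_per_type = 65L)
  co <- simulate_cohort(cfg)
  e <- normalize_log(co$counts[["CT1"]], co$cells, co$patients)
  truth <- co$truth$subtype_of_patient
  s1 <- names(truth)[truth == 1]
  take <- e$cells$patient_id %in% s1 | e$cells$diagnosis == "control"
  expect_gt(sum(take), 1400)
  out <- de_features(e$values[, take], e$cells$patient_id[take] %in% s1,
                     e$cells[take, ], comparison = "vs_controls",
                     thresholds = de_thresholds())
  expect_lte(nrow(out) / nrow(e$values), 0.10)
})
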