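## Subtype-specific differential expression: two-part hurdle model with
## likelihood-ratio tests for genes, empirical-Bayes moderated linear model
## for gene-set scores, thresholding, intersection, uniqueness, discordance.

#' DE thresholds
#' @param logfc_min minimum absolute log2 fold change (0.14 ~ a 10% change).
#' @param fdr_max BH FDR cutoff.
#' @return list of class \code{de_thresholds}.
#' @export
de_thresholds <- function(logfc_min = 0.14, fdr_max = 0.05) {
  if (logfc_min < 0) stopf("logfc_min must be >= 0")
  if (fdr_max <= 0 || fdr_max >= 1) stopf("fdr_max must be in (0, 1)")
  structure(list(logfc_min = logfc_min, fdr_max = fdr_max),
            class = "de_thresholds")
}

# Nested design pair with aliased columns dropped consistently.
prepare_designs <- function(full, reduced) {
  full <- drop_aliased(as.matrix(full))
  reduced <- as.matrix(reduced)
  reduced <- reduced[, colnames(reduced) %in% colnames(full), drop = FALSE]
  reduced <- drop_aliased(reduced)
  if (!all(colnames(reduced) %in% colnames(full)))
    stopf("reduced design is not nested in the full design")
  list(full = full, reduced = reduced)
}

# Logistic deviance with a small-ridge IRLS fallback under separation.
logistic_deviance <- function(X, y, ridge = FALSE, lambda = 1e-2) {
  if (!ridge) {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    sep <- !fit$converged || any(abs(fit$coefficients) > 15, na.rm = TRUE)
    if (!sep)
      return(list(deviance = fit$deviance, coef = fit$coefficients,
                  flagged = FALSE))
  }
  beta <- numeric(ncol(X))
  for (i in 1:50) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    A <- crossprod(X, w * X) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  p <- plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  list(deviance = dev, coef = drop(beta), flagged = TRUE)
}

#' Hurdle-model likelihood-ratio test for one feature
#'
#' Discrete part: logistic regression of detection (y > 0) on the design.
#' Continuous part: Gaussian linear model of y over expressed cells. The
#' LRT statistic is the sum of both parts' deviance differences between the
#' full and reduced (nested) designs, referred to a chi-square with the
#' total added degrees of freedom. The reported log2 fold change is the
#' hurdle combined mean pi * mu evaluated at the covariate means with the
#' test column(s) set to 1 vs 0.
#'
#' @param y per-cell expression of one feature (log2 scale).
#' @param full_design,reduced_design numeric design matrices with named
#'   columns; the reduced design must be nested in the full one.
#' @param min_cont_cells minimum expressed cells to fit the continuous part.
#' @return list with p, log2fc, stat, df and component diagnostics.
#' @export
hurdle_lrt <- function(y, full_design, reduced_design, min_cont_cells = NULL) {
  ds <- prepare_designs(full_design, reduced_design)
  Xf <- ds$full; Xr <- ds$reduced
  test_cols <- setdiff(colnames(Xf), colnames(Xr))
  if (all(y == 0))
    return(list(p = 1, log2fc = 0, stat = 0, df = 0L, flag = "all_zero"))

  ybin <- as.numeric(y > 0)
  fit_f <- logistic_deviance(Xf, ybin)
  fit_r <- logistic_deviance(Xr, ybin, ridge = fit_f$flagged)
  if (fit_r$flagged && !fit_f$flagged) fit_f <- logistic_deviance(Xf, ybin, ridge = TRUE)
  stat_disc <- max(0, fit_r$deviance - fit_f$deviance)
  df_disc <- ncol(Xf) - ncol(Xr)

  pos <- y > 0
  if (is.null(min_cont_cells)) min_cont_cells <- ncol(Xf) + 2
  stat_cont <- 0; df_cont <- 0L; beta_cont <- NULL; cont_cols <- NULL
  if (sum(pos) >= min_cont_cells) {
    Xfp <- drop_aliased(Xf[pos, , drop = FALSE])
    Xrp <- Xr[pos, colnames(Xr) %in% colnames(Xfp), drop = FALSE]
    Xrp <- drop_aliased(Xrp)
    lf <- lm.fit(Xfp, y[pos])
    lr <- lm.fit(Xrp, y[pos])
    rss_f <- sum(lf$residuals^2)
    rss_r <- sum(lr$residuals^2)
    if (rss_f > 0) {
      stat_cont <- sum(pos) * log(rss_r / rss_f)
      df_cont <- ncol(Xfp) - ncol(Xrp)
      beta_cont <- lf$coefficients
      cont_cols <- colnames(Xfp)
    }
  }
  stat <- stat_disc + stat_cont
  df <- df_disc + df_cont
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1

  ## combined fold change: pi * mu at covariate means, test columns 1 vs 0
  xbar <- colMeans(Xf)
  x1 <- x0 <- xbar
  x1[test_cols] <- 1; x0[test_cols] <- 0
  pi1 <- plogis(sum(x1 * fit_f$coef)); pi0 <- plogis(sum(x0 * fit_f$coef))
  if (!is.null(beta_cont)) {
    mu1 <- sum(x1[cont_cols] * beta_cont)
    mu0 <- sum(x0[cont_cols] * beta_cont)
  } else {
    mu1 <- mu0 <- if (any(pos)) mean(y[pos]) else 0
  }
  list(p = p, log2fc = pi1 * mu1 - pi0 * mu0, stat = stat, df = df,
       stat_disc = stat_disc, stat_cont = stat_cont,
       pi = c(pi0 = pi0, pi1 = pi1), mu = c(mu0 = mu0, mu1 = mu1),
       flag = if (fit_f$flagged) "ridge" else NA_character_)
}

# Full/reduced designs for the subtype test with the standard covariates.
build_de_designs <- function(group, covariates,
                             covariate_names = c("detection_rate", "age",
                                                 "sex", "RIN", "PMI", "region",
                                                 "batch", "ribo_fraction")) {
  use <- intersect(covariate_names, names(covariates))
  df <- covariates[, use, drop = FALSE]
  df$.group <- as.numeric(group)
  full <- model.matrix(
    stats::as.formula(paste("~ .group", if (length(use))
      paste("+", paste(use, collapse = " + ")) else "")), df)
  reduced <- full[, colnames(full) != ".group", drop = FALSE]
  list(full = full, reduced = reduced)
}

#' Differential features for one comparison
#'
#' Tests every feature (genes via the hurdle LRT, gene-set scores via the
#' moderated linear model) for a two-group contrast, applies BH FDR within
#' the family and keeps rows passing both the absolute log2 fold change and
#' FDR gates. The unthresholded table is attached as attribute
#' \code{"full"}.
#'
#' @param values features x cells matrix (log2 expression or set scores).
#' @param group logical/0-1 vector over cells: tested group membership.
#' @param covariates data.frame of per-cell covariates.
#' @param cell_type,subtype,comparison labels stored in the output rows.
#' @param thresholds a \code{\link{de_thresholds}}.
#' @param method "hurdle" (genes) or "moderated" (set scores).
#' @param feature_kind "gene" or "gene_set".
#' @return data.frame with columns feature, feature_kind, cell_type,
#'   subtype, comparison, log2fc, p, fdr, direction.
#' @export
de_features <- function(values, group, covariates,
                        cell_type = "all", subtype = 1L,
                        comparison = c("vs_other_subtypes", "vs_controls"),
                        thresholds = de_thresholds(),
                        method = c("hurdle", "moderated"),
                        feature_kind = c("gene", "gene_set")) {
  comparison <- match.arg(comparison)
  method <- match.arg(method)
  feature_kind <- match.arg(feature_kind)
  group <- as.logical(group)
  if (sum(group) < 3 || sum(!group) < 3)
    stopf("each group needs at least 3 cells (got %d / %d)",
          sum(group), sum(!group))
  ds <- build_de_designs(group, covariates)
  if (method == "hurdle") {
    res <- apply(values, 1, function(y)
      hurdle_lrt(y, ds$full, ds$reduced)[c("p", "log2fc")])
    p <- vapply(res, `[[`, numeric(1), "p")
    fc <- vapply(res, `[[`, numeric(1), "log2fc")
  } else {
    mod <- moderated_lm(values, ds$full, coef = ".group")
    p <- mod$p
    fc <- mod$log2fc
  }
  tab <- data.frame(feature = rownames(values), feature_kind = feature_kind,
                    cell_type = cell_type, subtype = subtype,
                    comparison = comparison, log2fc = fc, p = p,
                    fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  tab$direction <- ifelse(tab$log2fc >= 0, "up", "down")
  rownames(tab) <- NULL
  kept <- tab[abs(tab$log2fc) >= thresholds$logfc_min &
                tab$fdr < thresholds$fdr_max, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "full") <- tab
  kept
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated linear model for gene-set scores
#'
#' Per-feature ordinary least squares on a common design; residual variances
#' are shrunk towards a common prior estimated by method of moments on the
#' log sample variances (scaled inverse-chi-square prior with d0 df and
#' scale s0^2), and the moderated t uses d0 + d_g degrees of freedom. When
#' the moment estimate of the prior df is non-finite (log-variances no more
#' dispersed than chi-square sampling alone), d0 = Inf and every posterior
#' variance equals s0^2.
#'
#' @param values features x samples matrix.
#' @param design design matrix (full rank after alias dropping).
#' @param coef column name of the tested coefficient.
#' @param d0_override optionally force the prior df (0 = ordinary t,
#'   Inf = fully pooled).
#' @return data.frame with log2fc (the coefficient), t, p, df_total, s2_post
#'   per feature; prior df/scale attached as attributes.
#' @export
moderated_lm <- function(values, design, coef = ".group", d0_override = NULL) {
  X <- drop_aliased(as.matrix(design))
  if (!coef %in% colnames(X)) stopf("coefficient '%s' not in design", coef)
  n <- ncol(values)
  d_g <- n - ncol(X)
  if (d_g < 2) stopf("need at least 2 residual degrees of freedom")
  fit <- lm.fit(X, t(values))
  co <- fit$coefficients
  if (!is.matrix(co)) co <- matrix(co, ncol = 1, dimnames = list(names(co), NULL))
  beta <- co[coef, ]
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / d_g
  v <- chol2inv(chol(crossprod(X)))[which(colnames(X) == coef),
                                    which(colnames(X) == coef)]
  ## method-of-moments fit of the variance prior on log s^2
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d_g / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
  } else if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variances no more dispersed than chi-square sampling alone:
    # infinite prior df, pooled scale = mean sample variance
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d_g * s2) / (d0 + d_g)
  tstat <- beta / sqrt(s2_post * v)
  # total df capped at the pooled residual df (all genes), as in the
  # standard moderated-t treatment of an infinite prior
  df_tot <- min(d0 + d_g, length(s2) * d_g)
  p <- 2 * pt(-abs(tstat), df = df_tot)
  out <- data.frame(feature = rownames(values), log2fc = beta, t = tstat,
                    p = p, s2_post = s2_post, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_total") <- df_tot
  out
}

#' Subtype-specific features: intersection of the two comparisons
#'
#' Features differential both versus the other subtypes and versus controls;
#' reported effect and direction come from the vs-other-subtypes comparison.
#'
#' @param de_vs_subtypes,de_vs_controls thresholded \code{\link{de_features}}
#'   tables for the same (subtype, cell type).
#' @return the vs-other-subtypes rows restricted to the intersection.
#' @export
subtype_specific <- function(de_vs_subtypes, de_vs_controls) {
  keep <- de_vs_subtypes$feature %in% de_vs_controls$feature
  out <- de_vs_subtypes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition subtype-specific features into unique and common
#'
#' Within one cell type, a feature is unique if it appears in exactly one
#' subtype's table and common if it appears in all of them.
#'
#' @param tables named list (one thresholded table per subtype).
#' @param top_n how many top features (by |log2fc|) to report per subtype.
#' @return list with \code{unique} (data.frame subtype, feature, log2fc),
#'   \code{common} (feature ids), \code{top_unique} (head of unique per
#'   subtype ranked by |log2fc|).
#' @export
partition_unique_common <- function(tables, top_n = 10L) {
  feats <- lapply(tables, function(t) unique(t$feature))
  all_feats <- unique(unlist(feats))
  count <- vapply(all_feats, function(f)
    sum(vapply(feats, function(x) f %in% x, logical(1))), integer(1))
  common <- all_feats[count == length(tables)]
  uniq <- do.call(rbind, lapply(names(tables), function(s) {
    t <- tables[[s]]
    u <- t[t$feature %in% all_feats[count == 1] & t$feature %in% feats[[s]], ,
           drop = FALSE]
    if (nrow(u)) data.frame(subtype = s, feature = u$feature,
                            log2fc = u$log2fc, stringsAsFactors = FALSE)
  }))
  top_unique <- if (!is.null(uniq) && nrow(uniq)) {
    do.call(rbind, lapply(split(uniq, uniq$subtype), function(d)
      head(d[order(-abs(d$log2fc)), , drop = FALSE], top_n)))
  }
  list(unique = uniq, common = common, top_unique = top_unique)
}

#' Discordant regulatory direction among subtypes
#'
#' For features common to all subtypes, compares the signs of the
#' vs-controls log2 fold changes across subtypes; an event is a feature
#' whose signs are not all equal, attributed to the minority-sign
#' subtype(s). Zero fold changes cast no vote.
#'
#' @param common_features feature ids common to all subtypes.
#' @param fc_vs_controls data.frame with columns feature, subtype,
#'   log2fc (vs controls), and optionally cell_type.
#' @return data.frame of events: feature, cell_type, subtype.
#' @export
discordant_events <- function(common_features, fc_vs_controls) {
  out <- list()
  for (f in common_features) {
    rows <- fc_vs_controls[fc_vs_controls$feature == f, , drop = FALSE]
    signs <- sign(rows$log2fc)
    voting <- rows[signs != 0, , drop = FALSE]
    vs <- sign(voting$log2fc)
    if (length(vs) < 2 || length(unique(vs)) < 2) next
    minority_sign <- if (sum(vs > 0) < sum(vs < 0)) 1 else -1
    culprit <- voting$subtype[sign(voting$log2fc) == minority_sign]
    ct <- if ("cell_type" %in% names(rows)) rows$cell_type[1] else NA_character_
    out[[length(out) + 1]] <- data.frame(
      feature = f, cell_type = ct, subtype = culprit,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(feature = character(), cell_type = character(),
                  subtype = character(), stringsAsFactors = FALSE)
}
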