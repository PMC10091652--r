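## PLS-DA subtype prediction: NIPALS PLS2 on one-hot labels with argmax
## decoding, three data-splitting schemes, repeated stratified CV over the
## number of components, micro/macro/weighted F1.

#' Prediction parameters
#'
#' @param scheme "random_cells" (stratified 7:3 cell split),
#'   "leave_patient_out" (one held-out patient per subtype, cell level) or
#'   "patient_level" (per-patient mean profiles, one held-out patient per
#'   subtype, repeated).
#' @param train_fraction training fraction for the random-cells scheme.
#' @param cv_folds,cv_repeats inner CV geometry (10x10 for the cell-level
#'   schemes, 3x10 for the patient-level scheme).
#' @param component_grid candidate numbers of PLS components.
#' @param outer_repeats outer split repeats for the patient-level scheme.
#' @param seed split / CV seed.
#' @return list of class \code{prediction_params}.
#' @export
prediction_params <- function(scheme = c("random_cells", "leave_patient_out",
                                         "patient_level"),
                              train_fraction = 0.7,
                              cv_folds = NULL, cv_repeats = 10L,
                              component_grid = 1:5, outer_repeats = 10L,
                              seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.null(cv_folds)) cv_folds <- if (scheme == "patient_level") 3L else 10L
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  if (any(component_grid < 1)) stopf("component_grid entries must be >= 1")
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 component_grid = as.integer(component_grid),
                 outer_repeats = as.integer(outer_repeats),
                 seed = as.integer(seed)),
            class = "prediction_params")
}

#' Fit a PLS-DA model (NIPALS PLS2, one-hot targets)
#'
#' @param X samples x features matrix.
#' @param y class labels (>= 2 classes).
#' @param n_components number of latent components (>= 1, at most the rank
#'   of the centered X).
#' @return object of class \code{pls_da}: centering vectors, weights,
#'   loadings and the regression matrix.
#' @export
pls_da_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  if (n_components < 1) stopf("n_components must be >= 1")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stopf("n_components exceeds min(n_samples - 1, n_features)")
  Y <- vapply(levels(y), function(l) as.numeric(y == l), numeric(length(y)))
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  p <- ncol(X); k <- ncol(Y); A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, k, A)
  for (a in seq_len(A)) {
    if (sum(Xc^2) < 1e-12)
      stopf("n_components exceeds the rank of the centered X")
    u <- Yc[, which.max(apply(Yc, 2, var))]
    if (all(u == 0)) u <- Yc[, 1]
    t_old <- rep(Inf, nrow(X))
    for (it in 1:500) {
      w <- drop(crossprod(Xc, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-12 * sum(tt^2)) break
      t_old <- tt
    }
    pl <- drop(crossprod(Xc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q,
                 B = B, classes = levels(y), n_components = A),
            class = "pls_da")
}

#' Predict classes from a PLS-DA model
#' @param object a \code{\link{pls_da_fit}} model.
#' @param newdata samples x features matrix with the training feature set.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.pls_da <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean)
  scores <- Xc %*% object$B
  scores <- sweep(scores, 2, object$y_mean, "+")
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Stratified random cell split
#'
#' Per class, round(fraction * n) cells (half up) go to training; disjoint
#' and exhaustive.
#'
#' @param ids cell identifiers.
#' @param labels class per cell.
#' @param fraction training fraction.
#' @param seed split seed.
#' @return list(train, test) of ids.
#' @export
split_random_cells <- function(ids, labels, fraction = 0.7, seed = 1L) {
  with_seed(seed, {
    train <- unlist(lapply(split(ids, labels), function(x) {
      n_train <- floor(length(x) * fraction + 0.5)
      sample(x, n_train)
    }), use.names = FALSE)
    list(train = train, test = setdiff(ids, train))
  })
}

#' Leave one patient per subtype out (cell level)
#'
#' @param ids cell identifiers.
#' @param patient_of_cell patient id per cell.
#' @param subtype_of_patient named subtype per patient.
#' @param seed selection seed.
#' @return list(train, test, test_patients); no patient spans both sides.
#' @export
split_leave_patient_out <- function(ids, patient_of_cell, subtype_of_patient,
                                    seed = 1L) {
  sizes <- table(subtype_of_patient)
  if (any(sizes < 2)) stopf("every subtype needs >= 2 patients")
  with_seed(seed, {
    test_pat <- vapply(split(names(subtype_of_patient), subtype_of_patient),
                       function(p) sample(p, 1), character(1))
    test <- ids[patient_of_cell %in% test_pat]
    list(train = setdiff(ids, test), test = test, test_patients = test_pat)
  })
}

#' Patient-level split on mean profiles
#'
#' @param profiles patients x features matrix.
#' @param labels named subtype per patient.
#' @param seed selection seed.
#' @return list(train, test) of patient ids.
#' @export
split_patient_level <- function(profiles, labels, seed = 1L) {
  sizes <- table(labels)
  if (any(sizes < 2)) stopf("every subtype needs >= 2 patients")
  with_seed(seed, {
    test_pat <- vapply(split(names(labels), labels),
                       function(p) sample(p, 1), character(1))
    list(train = setdiff(rownames(profiles), test_pat),
         test = unname(test_pat))
  })
}

#' Choose the number of PLS components by repeated stratified CV
#'
#' Mean accuracy over folds x repeats per grid value; ties go to the
#' smallest number of components. Grid values exceeding what the smallest
#' training fold supports are skipped.
#'
#' @param X samples x features training matrix.
#' @param y training labels.
#' @param params a \code{\link{prediction_params}}.
#' @return list(best, accuracy) with the per-grid mean accuracies.
#' @export
cv_select <- function(X, y, params) {
  y <- as.factor(y)
  n <- nrow(X)
  fold_min <- floor(n * (params$cv_folds - 1) / params$cv_folds)
  grid <- params$component_grid
  grid <- grid[grid <= min(fold_min - 1, ncol(X))]
  if (length(grid) == 0) stopf("component grid empty after rank capping")
  acc <- setNames(numeric(length(grid)), grid)
  cnt <- 0
  with_seed(params$seed, {
    for (rep in seq_len(params$cv_repeats)) {
      folds <- integer(n)
      for (cl in levels(y)) {
        idx <- which(y == cl)
        folds[idx] <- sample(rep_len(seq_len(params$cv_folds), length(idx)))
      }
      for (f in seq_len(params$cv_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < nlevels(y)) next
        for (gi in seq_along(grid)) {
          fit <- tryCatch(pls_da_fit(X[tr, , drop = FALSE], y[tr], grid[gi]),
                          error = function(e) NULL)
          if (is.null(fit)) next
          pred <- predict(fit, X[!tr, , drop = FALSE])
          acc[gi] <- acc[gi] + mean(pred == y[!tr])
        }
        cnt <- cnt + 1
      }
    }
  })
  acc <- acc / cnt
  list(best = grid[which.max(acc)], accuracy = acc)
}

#' Micro, macro and weighted F1
#'
#' Per-class precision/recall/F1 (zero where undefined); micro-F1 from
#' pooled counts (equal to accuracy for single-label multiclass), macro the
#' unweighted mean, weighted the support-weighted mean.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return list(micro_f1, macro_f1, weighted_f1, accuracy, per_class).
#' @export
f1_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stopf("empty input")
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- factor(y_true, levels = classes)
  y_pred <- factor(y_pred, levels = classes)
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(y_pred == cl & y_true == cl)
    fp[cl] <- sum(y_pred == cl & y_true != cl)
    fn[cl] <- sum(y_pred != cl & y_true == cl)
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  micro <- if (sum(tp + fp) > 0 && sum(tp + fn) > 0) {
    mp <- sum(tp) / sum(tp + fp); mr <- sum(tp) / sum(tp + fn)
    if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  } else 0
  list(micro_f1 = micro, macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / sum(support),
       accuracy = mean(y_true == y_pred),
       per_class = data.frame(class = classes, precision = prec,
                              recall = rec, f1 = f1, support = support))
}

#' Run one prediction scheme end to end
#'
#' Splits the data per the scheme, tunes the number of components by
#' repeated stratified CV on the training side only, fits the final model
#' and reports test-set metrics. The patient-level scheme repeats the outer
#' split \code{outer_repeats} times and also reports the mean accuracy.
#'
#' @param values features x cells (or features x patients) matrix.
#' @param sample_patient patient id per column.
#' @param subtype_of_patient named subtype per patient (cases only).
#' @param params a \code{\link{prediction_params}}.
#' @return list of class \code{prediction_report}.
#' @export
run_prediction <- function(values, sample_patient, subtype_of_patient,
                           params = prediction_params()) {
  keep <- sample_patient %in% names(subtype_of_patient)
  values <- values[, keep, drop = FALSE]
  sample_patient <- sample_patient[keep]
  y_cell <- factor(unname(subtype_of_patient[sample_patient]))
  X <- t(values)
  ids <- colnames(values)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(values)))
  rownames(X) <- ids

  if (params$scheme == "patient_level") {
    prof <- vapply(names(subtype_of_patient), function(p)
      rowMeans(values[, sample_patient == p, drop = FALSE]),
      numeric(nrow(values)))
    prof <- t(prof)
    labs <- factor(subtype_of_patient[rownames(prof)])
    accs <- numeric(params$outer_repeats)
    metrics <- NULL
    for (r in seq_len(params$outer_repeats)) {
      sp <- split_patient_level(prof, subtype_of_patient,
                                seed = params$seed + r - 1L)
      inner <- params; inner$seed <- params$seed + 1000L + r
      sel <- cv_select(prof[sp$train, , drop = FALSE],
                       labs[match(sp$train, rownames(prof))], inner)
      fit <- pls_da_fit(prof[sp$train, , drop = FALSE],
                        labs[match(sp$train, rownames(prof))], sel$best)
      pred <- predict(fit, prof[sp$test, , drop = FALSE])
      truth <- labs[match(sp$test, rownames(prof))]
      m <- f1_metrics(truth, pred)
      accs[r] <- m$accuracy
      if (r == 1) metrics <- c(m, list(n_components = sel$best))
    }
    return(structure(c(metrics, list(scheme = params$scheme,
                                     mean_accuracy = mean(accs),
                                     accuracies = accs)),
                     class = "prediction_report"))
  }

  sp <- if (params$scheme == "random_cells") {
    split_random_cells(ids, y_cell, params$train_fraction, params$seed)
  } else {
    split_leave_patient_out(ids, sample_patient, subtype_of_patient,
                            params$seed)
  }
  tr_idx <- match(sp$train, ids)
  te_idx <- match(sp$test, ids)
  sel <- cv_select(X[tr_idx, , drop = FALSE], y_cell[tr_idx], params)
  fit <- pls_da_fit(X[tr_idx, , drop = FALSE], y_cell[tr_idx], sel$best)
  pred <- predict(fit, X[te_idx, , drop = FALSE])
  m <- f1_metrics(y_cell[te_idx], pred)
  structure(c(m, list(scheme = params$scheme, n_components = sel$best,
                      n_train = length(tr_idx), n_test = length(te_idx),
                      test_patients = sp$test_patients)),
            class = "prediction_report")
}
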