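# Stratified two-fold cross-validation of the inflammation model, and the
# named CT / MRI model builders.

#' Two-fold cross-validated evaluation
#'
#' Randomly splits the cohort into two stratified folds (for 15 subjects:
#' 7 and 8, both classes present in each fold by construction). Each fold
#' is used once for fitting and once for validation; every fold yields a
#' ROC curve on its held-out subjects. The report carries both the mean of
#' the two fold AUCs and the AUC of the vertically averaged curve.
#'
#' @param data Data frame with the feature columns.
#' @param features Character vector of predictor column names.
#' @param labels Binary outcome (two-level factor / 0-1), length
#'   `nrow(data)`.
#' @param seed Integer seed controlling the split.
#' @param lambda Ridge penalty handed to [fit_logistic()] (default 1e-3;
#'   small-cohort fits are frequently separable).
#' @return An object of class `cv_report`: per-fold train/test indices,
#'   fold `roc_curve`s and AUCs, the averaged curve, `mean_auc`, and the
#'   fold models.
#' @export
two_fold_cv <- function(data, features, labels, seed = NULL, lambda = 1e-3) {
  assert_that(all(features %in% names(data)),
              paste0("missing feature column(s): ",
                     paste(setdiff(features, names(data)), collapse = ", ")))
  y <- to_binary(labels)
  n <- length(y)
  assert_that(n >= 6, "cohort too small for two-fold cross-validation")
  assert_that(sum(y == 0) >= 2 && sum(y == 1) >= 2,
              "need at least 2 subjects per class")
  X <- as.matrix(data[, features, drop = FALSE])

  fold1 <- with_seed(seed, {
    idx0 <- sample(which(y == 0))
    idx1 <- sample(which(y == 1))
    # half of each class (floor on one, ceiling implied on the other fold)
    sort(c(idx0[seq_len(floor(length(idx0) / 2))],
           idx1[seq_len(ceiling(length(idx1) / 2))]))
  })
  folds <- list(fold1, setdiff(seq_len(n), fold1))

  eval_fold <- function(train, test) {
    fit <- fit_logistic(X[train, , drop = FALSE], y[train], lambda = lambda)
    scores <- plogis(fit$intercept +
                       drop(X[test, , drop = FALSE] %*% fit$coefficients))
    list(fit = fit, roc = roc_points(scores, y[test]))
  }
  f1 <- eval_fold(folds[[1]], folds[[2]])
  f2 <- eval_fold(folds[[2]], folds[[1]])
  rocs <- list(f1$roc, f2$roc)
  avg <- average_roc(rocs)
  structure(list(folds = folds, features = features,
                 fold_rocs = rocs,
                 fold_aucs = c(f1$roc$auc, f2$roc$auc),
                 mean_auc = mean(c(f1$roc$auc, f2$roc$auc)),
                 average_roc = avg, average_curve_auc = avg$auc,
                 fold_models = list(f1$fit, f2$fit),
                 seed = seed, lambda = lambda, n = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Two-fold cross-validation (n = %d; folds %d/%d)\n",
              x$n, length(x$folds[[1]]), length(x$folds[[2]])))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  fold AUCs: %.3f, %.3f; mean AUC = %.3f; averaged-curve AUC = %.3f\n",
              x$fold_aucs[1], x$fold_aucs[2], x$mean_auc,
              x$average_curve_auc))
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  plot(x$fold_rocs[[1]], col = "forestgreen",
       main = sprintf("Two-fold CV (mean AUC %.3f)", x$mean_auc), ...)
  plot(x$fold_rocs[[2]], add = TRUE, col = "steelblue")
  plot(x$average_roc, add = TRUE, col = "red", lwd = 2)
  graphics::legend("bottomright", legend = c(
    sprintf("fold 1 (%.3f)", x$fold_aucs[1]),
    sprintf("fold 2 (%.3f)", x$fold_aucs[2]),
    sprintf("average (%.3f)", x$average_curve_auc)),
    col = c("forestgreen", "steelblue", "red"), lwd = c(1, 1, 2), bty = "n")
  invisible(x)
}

# canonical predictor sets of the two published model compositions
ct_model_features <- function() c("ct_average_gray", "ct_hist_kurtosis",
                                  "ct_cooc_entropy", "NLR", "GM_CSF")
mri_model_features <- function() c("mr_hist_kurtosis", "NLR", "GM_CSF")

#' Build and cross-validate the CT and MRI inflammation models
#'
#' The CT model uses average gray, histogram kurtosis, co-occurrence
#' entropy, NLR and GM-CSF (5 features + constant); the MRI model uses
#' histogram kurtosis, NLR and GM-CSF (3 features + constant). Labels come
#' from median dichotomization of the cohort's CD45 values unless a
#' `group` column supplies them.
#'
#' @param cohort Data frame containing the named feature columns plus
#'   `cd45` (or a two-level `group` column).
#' @param seed Split seed passed to [two_fold_cv()].
#' @param lambda Ridge penalty for the fold fits.
#' @return List with elements `ct` and `mri`, each holding the `cv_report`
#'   and the full-cohort `infl_logit` fit.
#' @export
run_models <- function(cohort, seed = NULL, lambda = 1e-3) {
  labels <- if ("cd45" %in% names(cohort)) {
    dichotomize_by_median(cohort$cd45)
  } else if ("group" %in% names(cohort)) {
    factor(cohort$group, levels = c("low", "high"))
  } else stop_pr("cohort needs a cd45 or group column")
  assert_that(nlevels(droplevels(as.factor(labels))) == 2,
              "cohort is single-class after dichotomization")

  build <- function(features, idx) {
    missing <- setdiff(features, names(cohort))
    assert_that(length(missing) == 0,
                paste0("cohort lacks model feature(s): ",
                       paste(missing, collapse = ", ")))
    cv <- two_fold_cv(cohort, features, labels,
                      seed = child_seed(seed, idx), lambda = lambda)
    full <- fit_logistic(as.matrix(cohort[, features, drop = FALSE]),
                         labels, lambda = lambda)
    list(cv = cv, fit = full, features = features)
  }
  list(ct = build(ct_model_features(), 1L),
       mri = build(mri_model_features(), 2L))
}
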