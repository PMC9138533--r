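# ROC construction, AUC equivalences, curve averaging and two-fold CV.

test_that("textbook score configurations give their known AUCs", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
})

test_that("curves are monotone from (0,0) to (1,1) and integrate to auc", {
  set.seed(70)
  r <- roc_points(rnorm(40), rbinom(40, 1, 0.5))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(r$auc, trap)
})

test_that("trapezoidal AUC equals the rank-based AUC on random instances", {
  set.seed(71)
  for (i in 1:500) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
    expect_equal(auc(s, y), rank_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(72)
  y <- rbinom(50, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(50)
  a0 <- auc(s, y)
  expect_equal(auc(exp(s), y), a0, tolerance = 1e-12)
  expect_equal(auc(plogis(3 * s + 2), y), a0, tolerance = 1e-12)
})

test_that("trapezoidal AUC matches pROC's numeric AUC", {
  set.seed(73)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
    s <- rnorm(30)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(s, y), ref, tolerance = 1e-10)
  }
})

test_that("vertical averaging of identical curves is the identity", {
  set.seed(74)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  r <- roc_points(rnorm(30), y)
  avg <- average_roc(list(r, r))
  expect_equal(avg$tpr, pneumorad:::roc_interpolate(r, avg$fpr),
               tolerance = 1e-12)
  # averaging a perfect and a null curve lands in between
  rp <- roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))
  rn <- roc_points(c(4, 3, 2, 1), c(0, 0, 1, 1))
  mid <- average_roc(list(rp, rn))
  expect_equal(mid$auc, 0.5, tolerance = 0.02)
})

test_that("two-fold CV builds stratified 7/8 folds and is seed-reproducible", {
  coh <- generate_tabular_cohort(cohort_spec(seed = 80))
  coh$NLR <- derive_ratios(coh)$NLR
  labels <- dichotomize_by_median(coh$cd45)
  cv <- two_fold_cv(coh, c("NLR", "GM_CSF"), labels, seed = 4)
  expect_equal(sort(lengths(cv$folds)), c(7L, 8L))
  expect_setequal(unlist(cv$folds), 1:15)
  for (f in cv$folds) expect_equal(nlevels(droplevels(labels[f])), 2)
  expect_equal(cv$mean_auc, mean(cv$fold_aucs))

  cv2 <- two_fold_cv(coh, c("NLR", "GM_CSF"), labels, seed = 4)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$mean_auc, cv2$mean_auc)
  cv3 <- two_fold_cv(coh, c("NLR", "GM_CSF"), labels, seed = 5)
  expect_false(identical(cv$folds, cv3$folds))
})

test_that("run_models builds the published CT and MRI compositions", {
  coh <- generate_tabular_cohort(cohort_spec(seed = 81))
  coh$NLR <- derive_ratios(coh)$NLR
  reports <- run_models(coh, seed = 2)
  expect_named(reports, c("ct", "mri"))
  expect_length(reports$ct$features, 5)
  expect_length(reports$mri$features, 3)
  expect_length(coef(reports$ct$fit), 6)    # 5 features + model constant
  expect_length(coef(reports$mri$fit), 4)
  expect_true(all(c("NLR", "GM_CSF") %in% reports$ct$features))

  noGM <- coh; noGM$GM_CSF <- NULL
  expect_error(run_models(noGM), "GM_CSF")
  singleclass <- coh; singleclass$cd45 <- rep(1, 15)
  expect_error(run_models(singleclass))
})

test_that("cohorts too small or single-class cannot be cross-validated", {
  df <- data.frame(x = rnorm(4))
  expect_error(two_fold_cv(df, "x", c(0, 1, 0, 1)), "too small")
  df8 <- data.frame(x = rnorm(8))
  expect_error(two_fold_cv(df8, "x", c(1, 1, 1, 1, 1, 1, 0, 1)),
               "2 subjects per class")
})
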