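# Median dichotomization, ANOVA screening, and correlation pruning.

test_that("median dichotomization splits 15 distinct values into 7 and 8", {
  set.seed(30)
  x <- sample(seq(0.1, 0.41, length.out = 15))
  g <- dichotomize_by_median(x)
  expect_equal(unname(table(g)["low"]), 7L)
  expect_equal(unname(table(g)["high"]), 8L)
  # the median subject itself lands in the high group
  expect_equal(unname(g[which(x == median(x))]), factor("high",
               levels = c("low", "high"))[[1]])
})

test_that("even cohorts split in half and degenerate inputs error", {
  g <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_equal(as.vector(table(g)), c(2, 2))
  expect_error(dichotomize_by_median(rep(2, 6)), "identical")
  expect_error(dichotomize_by_median(c(1, 2)), "at least 4")
})

test_that("identical groups give F = 0 and p = 1", {
  p <- anova_p(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(p, 1)
})

test_that("the two-group F statistic equals the squared pooled t", {
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    x <- c(rnorm(n1), rnorm(n2, sample(0:2, 1)))
    g <- rep(c("lo", "hi"), c(n1, n2))
    p_f <- anova_p(x, g)
    tt <- t.test(x ~ g, var.equal = TRUE)
    expect_equal(p_f, tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA p agrees with a permutation test on small samples", {
  set.seed(32)
  x <- c(rnorm(7, 0), rnorm(8, 1.2))
  g <- rep(c("low", "high"), c(7, 8))
  p_f <- anova_p(x, g)
  obs <- abs(mean(x[g == "high"]) - mean(x[g == "low"]))
  perm <- replicate(4000, {
    gg <- sample(g)
    abs(mean(x[gg == "high"]) - mean(x[gg == "low"]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_f - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)
})

test_that("correlated survivors are pruned in ascending-p order", {
  set.seed(33)
  n <- 40
  g <- rep(c("low", "high"), each = n / 2)
  f1 <- rnorm(n) + (g == "high") * 3
  f2 <- f1 + rnorm(n, 0, 0.3)         # strongly correlated, weaker
  f3 <- rnorm(n)                      # uninformative
  df <- data.frame(f1 = f1, f2 = f2, f3 = f3)
  sel <- select_features(df, c("f1", "f2", "f3"), g)
  expect_true("f1" %in% sel$kept || "f2" %in% sel$kept)
  expect_false(all(c("f1", "f2") %in% sel$kept))
  expect_false("f3" %in% sel$kept)
  pruned <- setdiff(c("f1", "f2"), sel$kept)
  row <- sel$table[sel$table$feature == pruned, ]
  expect_match(row$reason, "\\|r\\|")
})

test_that("constant features are dropped as degenerate, not fatal", {
  df <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = rep(7, 6))
  g <- rep(c("low", "high"), each = 3)
  sel <- select_features(df, c("a", "b"), g)
  expect_false("b" %in% sel$kept)
  expect_match(sel$table$reason[sel$table$feature == "b"], "degenerate")
})

test_that("kept set is invariant to input feature order", {
  set.seed(34)
  coh <- generate_tabular_cohort(cohort_spec(seed = 77))
  coh$NLR <- derive_ratios(coh)$NLR
  feats <- c("NLR", "GM_CSF", "ct_average_gray", "ct_hist_kurtosis",
             "ct_cooc_entropy", "mr_hist_kurtosis",
             grep("ct_nuis", names(coh), value = TRUE)[1:10])
  labels <- dichotomize_by_median(coh$cd45)
  s1 <- select_features(coh, feats, labels)
  s2 <- select_features(coh, rev(feats), labels)
  s3 <- select_features(coh, sample(feats), labels)
  expect_identical(s1$kept, s2$kept)
  expect_identical(s1$kept, s3$kept)
})

test_that("threshold monotonicity: wider screens never shrink the kept set", {
  coh <- generate_tabular_cohort(cohort_spec(seed = 88))
  coh$NLR <- derive_ratios(coh)$NLR
  feats <- c("NLR", "GM_CSF", "ct_average_gray", "ct_hist_kurtosis",
             "ct_cooc_entropy", "mr_hist_kurtosis")
  labels <- dichotomize_by_median(coh$cd45)
  k_tight <- select_features(coh, feats, labels, p_threshold = 0.02)$kept
  k_loose <- select_features(coh, feats, labels, p_threshold = 0.5)$kept
  expect_true(all(k_tight %in% k_loose))
  r_small <- select_features(coh, feats, labels, r_cutoff = 0.2)$kept
  r_large <- select_features(coh, feats, labels, r_cutoff = 0.95)$kept
  expect_gte(length(r_large), length(r_small))
})

test_that("an empty kept set is a valid, non-error result", {
  set.seed(35)
  df <- data.frame(a = rnorm(12), b = rnorm(12))
  g <- rep(c("low", "high"), each = 6)
  sel <- select_features(df, c("a", "b"), g, p_threshold = 1e-6)
  expect_length(sel$kept, 0)
  expect_equal(sort(sel$dropped), c("a", "b"))
})
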