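# Pair and triplet co-occurrence builders against brute-force enumeration,
# plus the derived texture features.

test_that("1D pair example matches hand enumeration", {
  q <- row_quantized(c(1, 1, 2, 2), ng = 2)
  g <- build_glcm(q, distance = 1)
  expect_equal(g$P, matrix(c(2, 1, 1, 2) / 6, 2, 2))
})

test_that("constant ROI concentrates all pair mass on the diagonal cell", {
  q <- row_quantized(rep(1, 5), ng = 2)
  g <- build_glcm(q)
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)
  f <- glcm_features(g)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["max_probability"]), 1)
  expect_equal(unname(f["contrast"]), 0)
})

test_that("pair matrix invariants: symmetric, non-negative, sums to one", {
  set.seed(10)
  for (i in 1:20) {
    q <- random_quantized(c(5, 4, 3), ng = 5)
    if (sum(!is.na(q$levels)) < 4) next
    g <- tryCatch(build_glcm(q), error = function(e) NULL)
    if (is.null(g)) next
    expect_true(all(g$P >= 0))
    expect_lt(abs(sum(g$P) - 1), 1e-9)
    expect_equal(g$P, t(g$P), tolerance = 1e-12)
  }
})

test_that("pair builder matches exhaustive enumeration on random volumes", {
  set.seed(11)
  checked <- 0
  while (checked < 200) {
    q <- random_quantized(c(4, 4, 3), ng = 4, p_mask = runif(1, 0.5, 1))
    g <- tryCatch(build_glcm(q), error = function(e) NULL)
    if (is.null(g)) next
    expect_equal(g$P, bf_glcm(q$levels, 4), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_equal(checked, 200)
})

test_that("triplet builder matches exhaustive enumeration on random volumes", {
  set.seed(12)
  checked <- 0
  while (checked < 200) {
    q <- random_quantized(c(4, 4, 3), ng = 3, p_mask = runif(1, 0.6, 1))
    t3 <- tryCatch(build_triplet_cooccurrence(q), error = function(e) NULL)
    if (is.null(t3)) next
    expect_equal(t3$T, bf_triplet(q$levels, 3), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_equal(checked, 200)
})

test_that("1D alternating rows give the enumerated triplet distributions", {
  # length-4 row: one window each of (1,2,1) and (2,1,2) -> 1 bit
  q4 <- build_triplet_cooccurrence(row_quantized(c(1, 2, 1, 2), ng = 2))
  expect_equal(q4$T[1, 2, 1], 0.5)
  expect_equal(q4$T[2, 1, 2], 0.5)
  expect_equal(unname(triplet_features(q4)["entropy"]), 1)
  # length-5 row: windows (1,2,1),(2,1,2),(1,2,1) -> cells 2/3 and 1/3
  t3 <- build_triplet_cooccurrence(row_quantized(c(1, 2, 1, 2, 1), ng = 2))
  expect_equal(t3$T[1, 2, 1], 2 / 3)
  expect_equal(t3$T[2, 1, 2], 1 / 3)
  expect_equal(sum(t3$T != 0), 2)
  f <- triplet_features(t3)
  expect_equal(unname(f["entropy"]), log2(3) - 2 / 3, tolerance = 1e-12)
  # constant ROI -> zero entropy
  qc <- row_quantized(rep(1, 6), ng = 2)
  expect_equal(unname(triplet_features(build_triplet_cooccurrence(qc))["entropy"]),
               0)
})

test_that("triplet tensor is reversal-symmetric and normalized", {
  set.seed(13)
  for (i in 1:20) {
    q <- random_quantized(c(5, 4, 4), ng = 4)
    t3 <- tryCatch(build_triplet_cooccurrence(q), error = function(e) NULL)
    if (is.null(t3)) next
    expect_lt(abs(sum(t3$T) - 1), 1e-9)
    expect_equal(t3$T, aperm(t3$T, c(3, 2, 1)), tolerance = 1e-12)
    expect_true(all(t3$T >= 0))
  }
})

test_that("too-small masks raise instead of returning empty structures", {
  q <- row_quantized(1, ng = 2)
  expect_error(build_glcm(q), "no voxel pairs")
  q2 <- row_quantized(c(1, 2), ng = 2)
  expect_error(build_triplet_cooccurrence(q2), "no collinear triplets")
})

test_that("uniform and two-cell matrices give textbook entropies", {
  # uniform over all 64^2 cells -> 12 bits (the Ng = 64 ceiling)
  P <- matrix(1 / 64^2, 64, 64)
  expect_equal(unname(glcm_features(P)["entropy"]), 12)
  # two equal cells -> 1 bit (placed symmetrically to satisfy P = t(P))
  P2 <- matrix(0, 4, 4); P2[2, 2] <- 0.5; P2[3, 3] <- 0.5
  expect_equal(unname(glcm_features(P2)["entropy"]), 1)
})

test_that("pooled-direction features are invariant under 90-degree rotation", {
  set.seed(14)
  arr <- array(rnorm(12^3), c(12, 12, 12))
  msk <- array(runif(12^3) < 0.7, c(12, 12, 12))
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  vol1 <- image_volume(arr, c(1, 1, 1), "CT")
  vol2 <- image_volume(rot(arr), c(1, 1, 1), "CT")
  m1 <- roi_mask(msk, c(1, 1, 1)); m2 <- roi_mask(rot(msk), c(1, 1, 1))
  f1 <- glcm_features(build_glcm(quantize(vol1, m1, 8)))
  f2 <- glcm_features(build_glcm(quantize(vol2, m2, 8)))
  expect_equal(f1, f2, tolerance = 1e-10)
  t1 <- triplet_features(build_triplet_cooccurrence(quantize(vol1, m1, 8)))
  t2 <- triplet_features(build_triplet_cooccurrence(quantize(vol2, m2, 8)))
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("entropy respects its theoretical bounds on random inputs", {
  set.seed(15)
  for (i in 1:10) {
    q <- random_quantized(c(6, 6, 4), ng = 8, p_mask = 0.9)
    g <- build_glcm(q)
    e <- unname(glcm_features(g)["entropy"])
    expect_gte(e, 0)
    expect_lte(e, 2 * log2(8))
  }
})
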