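# MRI normalization, quantization, geometric and first-order features.

test_that("MRI normalization maps the masked range onto [0, 255]", {
  set.seed(1)
  vol <- image_volume(array(rnorm(8^3, 50, 12), c(8, 8, 8)), c(0.5, 0.5, 0.5),
                      "MRI")
  mask <- toy_mask(vol, function(x) x > 45)
  nv <- normalize_mri(vol, mask)
  inside <- nv$data[mask$voxels]
  expect_equal(min(inside), 0)
  expect_equal(max(inside), 255)
  expect_identical(nv$data[!mask$voxels], vol$data[!mask$voxels])
})

test_that("MRI normalization is idempotent and affine-invariant", {
  set.seed(2)
  vol <- image_volume(array(rnorm(6^3, 100, 20), c(6, 6, 6)), c(0.5, 0.5, 0.5),
                      "MRI")
  mask <- roi_mask(array(TRUE, c(6, 6, 6)), c(0.5, 0.5, 0.5))
  n1 <- normalize_mri(vol, mask)
  n2 <- normalize_mri(n1, mask)
  expect_equal(n2$data, n1$data, tolerance = 1e-12)
  # global affine intensity change leaves the normalized ROI untouched
  vol2 <- image_volume(3.7 * vol$data + 42, vol$spacing, "MRI")
  n3 <- normalize_mri(vol2, mask)
  expect_equal(n3$data[mask$voxels], n1$data[mask$voxels], tolerance = 1e-10)
})

test_that("normalization rejects degenerate inputs", {
  vol <- image_volume(array(5, c(4, 4, 4)), c(1, 1, 1), "MRI")
  mask <- roi_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(normalize_mri(vol, mask), "zero variance")
  ct <- image_volume(array(1:8, c(2, 2, 2)), c(1, 1, 1), "CT")
  expect_error(normalize_mri(ct, roi_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))),
               "MRI")
})

test_that("quantization assigns equal-width bins with the max in bin Ng", {
  arr <- array(0, c(64, 1, 1)); arr[, 1, 1] <- 0:63
  vol <- image_volume(arr, c(1, 1, 1), "CT")
  mask <- roi_mask(array(TRUE, dim(arr)), c(1, 1, 1))
  q <- quantize(vol, mask, 64)
  expect_identical(as.integer(q$levels[, 1, 1]), 1:64)

  arr2 <- array(0, c(4, 1, 1)); arr2[, 1, 1] <- 0:3
  vol2 <- image_volume(arr2, c(1, 1, 1), "CT")
  q2 <- quantize(vol2, roi_mask(array(TRUE, dim(arr2)), c(1, 1, 1)), 2)
  expect_identical(as.integer(q2$levels[, 1, 1]), c(1L, 1L, 2L, 2L))

  const <- image_volume(array(7, c(3, 3, 3)), c(1, 1, 1), "CT")
  expect_error(quantize(const, roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))),
               "constant")
})

test_that("geometric features match closed forms for voxel and cube", {
  one <- roi_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), c(1, 1, 1))
  g1 <- geometric_features(one)
  expect_equal(unname(g1["volume_mm3"]), 1)
  expect_equal(unname(g1["surface_area_mm2"]), 6)

  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  gc <- geometric_features(roi_mask(cube, c(1, 1, 1)))
  expect_equal(unname(gc["volume_mm3"]), 1000)
  expect_equal(unname(gc["surface_area_mm2"]), 600)
  expect_equal(unname(gc["sphericity"]), (36 * pi)^(1 / 3) / 6,
               tolerance = 1e-12)
  # cube body diagonal between outermost voxel centers
  expect_equal(unname(gc["max_diameter_3d_mm"]), sqrt(3 * 81), tolerance = 1e-12)
  expect_equal(unname(gc["elongation"]), 1, tolerance = 1e-12)
  expect_equal(unname(gc["flatness"]), 1, tolerance = 1e-12)
})

test_that("face-counted sphericity of a digital ball approaches 2/3", {
  # staircase faces over-count a sphere's area by 3/2, so the face-counted
  # sphericity tends to (4 pi r^2)/(6 pi r^2) = 2/3 as r grows
  d <- c(41, 41, 41)
  ctr <- (d + 1) / 2
  coords <- arrayInd(seq_len(prod(d)), d)
  ball <- array(sqrt(rowSums(sweep(coords, 2, ctr)^2)) <= 18, d)
  gb <- geometric_features(roi_mask(ball, c(1, 1, 1)))
  expect_lt(abs(unname(gb["sphericity"]) - 2 / 3), 0.03)
  expect_equal(unname(gb["elongation"]), 1, tolerance = 0.01)
  expect_equal(unname(gb["flatness"]), 1, tolerance = 0.01)
})

test_that("first-order features match direct statistics", {
  set.seed(3)
  arr <- array(rnorm(10^3, 50, 5), c(10, 10, 10))
  vol <- image_volume(arr, c(1, 1, 1), "CT")
  mask <- toy_mask(vol, function(x) x > 48)
  fo <- first_order_features(vol, mask)
  x <- arr[mask$voxels]
  expect_equal(unname(fo["mean"]), mean(x))
  expect_equal(unname(fo["median"]), median(x))
  expect_equal(unname(fo["variance"]), var(x))
  expect_equal(unname(fo["energy"]), sum(x^2))
  expect_equal(unname(fo["iqr"]), unname(diff(quantile(x, c(0.25, 0.75)))))
  expect_equal(length(fo), 20)
})

test_that("kurtosis follows the Pearson (non-excess) convention", {
  # symmetric two-point distribution has kurtosis exactly 1
  arr <- array(rep(c(-1, 1), 32), c(8, 8, 1))
  vol <- image_volume(arr, c(1, 1, 1), "CT")
  mask <- roi_mask(array(TRUE, dim(arr)), c(1, 1, 1))
  expect_equal(unname(first_order_features(vol, mask)["kurtosis"]), 1)

  # large normal sample: kurtosis near 3 within 3 SE (SE ~ sqrt(24/n))
  set.seed(4)
  n <- 40^3
  voln <- image_volume(array(rnorm(n), c(40, 40, 40)), c(1, 1, 1), "CT")
  maskn <- roi_mask(array(TRUE, c(40, 40, 40)), c(1, 1, 1))
  k <- unname(first_order_features(voln, maskn)["kurtosis"])
  expect_lt(abs(k - 3), 3 * sqrt(24 / n))
})

test_that("first-order entropy is bounded by log2 of the bin count", {
  set.seed(5)
  vol <- image_volume(array(runif(6^3), c(6, 6, 6)), c(1, 1, 1), "CT")
  mask <- roi_mask(array(TRUE, c(6, 6, 6)), c(1, 1, 1))
  for (nb in c(4, 16, 64)) {
    e <- unname(first_order_features(vol, mask, n_bins = nb)["entropy"])
    expect_gte(e, 0)
    expect_lte(e, log2(nb))
  }
})
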