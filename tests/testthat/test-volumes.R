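# NIfTI round trips, voxel bookkeeping, and CT threshold segmentation.

test_that("NIfTI write/read round trip preserves grid, spacing, intensities", {
  arr <- array(as.double(sample.int(4096, 1000)), c(10, 10, 10))
  vol <- image_volume(arr, c(0.4, 0.4, 0.6), "CT", "offset-HU")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "CT")
  expect_equal(back$data, arr, tolerance = 0)
  expect_lt(max(abs(back$spacing - c(0.4, 0.4, 0.6))), 1e-5)
  unlink(f)
})

test_that("mask round trip is exact", {
  m <- roi_mask(array(c(TRUE, FALSE), c(6, 5, 4)), c(0.5, 0.5, 0.5))
  f <- tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  back <- read_mask(f)
  expect_identical(back$voxels, m$voxels)
  unlink(f)
})

test_that("invalid volumes are rejected", {
  expect_error(image_volume(array(1, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(read_volume(tempfile()), "no such file")
})

test_that("mask volume is count times voxel volume", {
  m <- roi_mask(array(rep(c(TRUE, FALSE), c(1000, 24)), c(32, 32, 1)),
                c(0.5, 0.5, 0.5))
  expect_equal(mask_volume_mm3(m), 1000 * 0.125)
  one <- roi_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(mask_volume_mm3(one), 1)
  empty <- roi_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_error(mask_volume_mm3(empty), "empty")
})

test_that("voxel bookkeeping reproduces the study's sufficiency counts", {
  expect_identical(voxel_count_for_volume(823.5, c(0.4, 0.4, 0.6)), 8578L)
  expect_identical(voxel_count_for_volume(823.5, c(0.5, 0.5, 0.5)), 6588L)
  expect_identical(voxel_count_for_volume(1, c(1, 1, 1)), 1L)
  expect_error(voxel_count_for_volume(10, c(0, 1, 1)), "positive")
})

test_that("voxel count is monotone non-increasing in each spacing component", {
  base <- c(0.4, 0.4, 0.6)
  v0 <- voxel_count_for_volume(500, base)
  for (a in 1:3) {
    up <- base; up[a] <- up[a] * 1.5
    expect_lte(voxel_count_for_volume(500, up), v0)
  }
})

test_that("threshold segmentation recovers the phantom lungs", {
  ph <- generate_phantom(phantom_spec("CT", seed = 31), "low")
  seg <- segment_lungs_ct(ph$volume, 800, 1200)
  expect_gte(dice(seg$voxels, ph$mask$voxels), 0.95)
  vol_err <- abs(mask_volume_mm3(seg) - mask_volume_mm3(ph$mask)) /
    mask_volume_mm3(ph$mask)
  expect_lt(vol_err, 0.10)
})

test_that("segmentation is idempotent on its own masked output", {
  ph <- generate_phantom(small_ct_spec(seed = 32), "high")
  seg1 <- segment_lungs_ct(ph$volume, 800, 1200, min_component_voxels = 20)
  masked <- ph$volume
  masked$data[!seg1$voxels] <- 0
  seg2 <- segment_lungs_ct(masked, 800, 1200, min_component_voxels = 20)
  expect_identical(seg1$voxels, seg2$voxels)
})

test_that("uniform sub-threshold volumes yield an error, not an empty mask", {
  vol <- image_volume(array(100, c(8, 8, 8)), c(1, 1, 1), "CT")
  expect_error(segment_lungs_ct(vol, 800, 1200), "empty")
})

test_that("a midline tube-like component is removed as trachea proxy", {
  arr <- array(0, c(40, 40, 40))
  arr[5:15, 15:25, 10:30] <- 1000    # left lung block
  arr[25:35, 15:25, 10:30] <- 1000   # right lung block
  arr[19:21, 19:21, 5:35] <- 1000    # thin central tube
  vol <- image_volume(arr, c(0.4, 0.4, 0.4), "CT", "offset-HU")
  seg <- segment_lungs_ct(vol, 800, 1200)
  expect_false(any(seg$voxels[19:21, 19:21, 5:35]))
  expect_true(all(seg$voxels[5:15, 15:25, 10:30]))
  segk <- segment_lungs_ct(vol, 800, 1200, keep_all_components = TRUE)
  expect_true(any(segk$voxels[20, 20, 5:35]))
})

test_that("connected component labelling separates disjoint blobs", {
  fg <- array(FALSE, c(10, 10, 4))
  fg[1:3, 1:3, 1:2] <- TRUE
  fg[7:9, 7:9, 3:4] <- TRUE
  fg[5, 5, 1] <- TRUE
  lab <- pneumorad:::label_components(fg)
  expect_equal(max(lab), 3)
  expect_equal(sort(tabulate(lab[lab > 0]), decreasing = TRUE)[1:2], c(18, 18))
  # diagonal touch merges under 26-connectivity
  fg2 <- array(FALSE, c(4, 4, 4))
  fg2[1, 1, 1] <- TRUE; fg2[2, 2, 2] <- TRUE
  expect_equal(max(pneumorad:::label_components(fg2)), 1)
})
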