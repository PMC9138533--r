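# Intensity normalization, gray-level quantization, geometric and
# first-order histogram features.

#' Normalize MRI intensities within a region of interest
#'
#' Z-scores the masked intensities (mean 0, sd 1 inside the mask) and then
#' maps the masked range linearly onto [0, 255]; voxels outside the mask are
#' left untouched. The result is invariant under any global affine intensity
#' change of the input, which removes inter-scan scale/offset variation.
#'
#' @param vol An MRI [image_volume].
#' @param mask An [roi_mask] with non-zero intensity variance inside it.
#' @return A new [image_volume] with convention `"normalized-0-255"`.
#' @export
normalize_mri <- function(vol, mask) {
  assert_that(inherits(vol, "image_volume"), "vol must be an image_volume")
  assert_that(identical(vol$modality, "MRI"),
              "intensity normalization is defined for MRI volumes")
  check_mask_matches(vol, mask)
  x <- vol$data[mask$voxels]
  assert_that(length(x) >= 2, "mask must contain at least 2 voxels")
  s <- sd(x)
  assert_that(s > 0, "masked intensities have zero variance")
  z <- (x - mean(x)) / s
  out <- vol$data
  out[mask$voxels] <- 255 * (z - min(z)) / (max(z) - min(z))
  image_volume(out, vol$spacing, vol$modality, "normalized-0-255")
}

#' Quantize a region of interest to Ng gray levels
#'
#' Equal-width bins spanning the masked intensity range; the masked maximum
#' falls in bin `n_levels`.
#'
#' @param vol An [image_volume].
#' @param mask A non-empty [roi_mask].
#' @param n_levels Number of gray levels (>= 2); 64 throughout the package.
#' @return An object of class `quantized_roi`: a full-grid integer array
#'   `levels` (NA outside the mask), `n_levels`, the `bin_edges`, and the
#'   source `spacing`.
#' @export
quantize <- function(vol, mask, n_levels = 64) {
  assert_that(inherits(vol, "image_volume"), "vol must be an image_volume")
  check_mask_matches(vol, mask)
  assert_that(n_levels >= 2, "n_levels must be at least 2")
  x <- vol$data[mask$voxels]
  assert_that(length(x) >= 1, "mask is empty")
  lo <- min(x); hi <- max(x)
  assert_that(hi > lo, "constant region of interest cannot be quantized")
  width <- (hi - lo) / n_levels
  lev <- array(NA_integer_, dim(vol$data))
  lev[mask$voxels] <- pmin(as.integer(floor((x - lo) / width)) + 1L,
                           as.integer(n_levels))
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 bin_edges = lo + width * 0:n_levels,
                 spacing = vol$spacing),
            class = "quantized_roi")
}

#' Geometric (shape) features of a mask
#'
#' Eight features: volume (mm^3), surface area (mm^2, face counting over
#' boundary voxels), surface-to-volume ratio (1/mm), sphericity
#' (pi^(1/3) (6V)^(2/3) / A; 1 for a perfect ball), maximum 3D diameter
#' (mm, largest distance between boundary-voxel centers), major axis length
#' (mm, 4 sqrt(lambda1) of the voxel-coordinate covariance), elongation
#' (sqrt(lambda2/lambda1)) and flatness (sqrt(lambda3/lambda1)).
#'
#' @param mask A non-empty [roi_mask].
#' @return Named numeric vector of 8 features.
#' @export
geometric_features <- function(mask) {
  assert_that(inherits(mask, "roi_mask"), "mask must be an roi_mask")
  fg <- mask$voxels
  n <- sum(fg)
  assert_that(n > 0, "mask is empty")
  sp <- mask$spacing
  vol <- n * prod(sp)

  # face counting: a face contributes when its neighbour is background/outside
  d <- dim(fg)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  boundary <- array(FALSE, d)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      src <- slice_shift_index(d, a, s)
      shifted[src$dst] <- fg[src$src]
      exposed <- fg & !shifted
      area <- area + sum(exposed) * face_area[a]
      boundary <- boundary | exposed
    }
  }
  sv <- area / vol
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area

  bcoord <- sweep(arrayInd(which(boundary), d), 2, sp, `*`)
  maxdiam <- if (nrow(bcoord) >= 2) {
    sq <- rowSums(bcoord^2)
    sqrt(max(outer(sq, sq, `+`) - 2 * tcrossprod(bcoord)))
  } else 0

  xyz <- sweep(arrayInd(which(fg), d), 2, sp, `*`)
  if (n >= 2) {
    ev <- pmax(eigen(cov(xyz), symmetric = TRUE, only.values = TRUE)$values, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  c(volume_mm3 = vol, surface_area_mm2 = area, surface_to_volume = sv,
    sphericity = sphericity, max_diameter_3d_mm = maxdiam,
    major_axis_mm = major, elongation = elong, flatness = flat)
}

# index helper: voxels of `dst` slab receive voxels of `src` slab when the
# array is shifted by one voxel along axis `a` in direction `s`.
slice_shift_index <- function(d, a, s) {
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (s > 0) { src[[a]] <- 1:(d[a] - 1); dst[[a]] <- 2:d[a] }
  else       { src[[a]] <- 2:d[a];       dst[[a]] <- 1:(d[a] - 1) }
  grid <- function(ix) {
    m <- as.matrix(expand.grid(ix))
    colnames(m) <- NULL
    m
  }
  list(src = grid(src), dst = grid(dst))
}

#' First-order histogram features of a masked volume
#'
#' Twenty features of the masked intensity distribution: mean ("average
#' gray"), median, min, max, range, variance, sd, skewness, kurtosis
#' (Pearson convention: a normal sample gives 3), energy (sum of squared
#' intensities), entropy (log2, over an `n_bins`-bin equal-width histogram),
#' 10th/25th/75th/90th percentiles, interquartile range, mean absolute
#' deviation, robust (median) absolute deviation, coefficient of variation
#' and uniformity (sum of squared histogram probabilities).
#'
#' @param vol An [image_volume].
#' @param mask An [roi_mask] with at least 2 voxels.
#' @param n_bins Histogram bins for entropy/uniformity (default 64).
#' @return Named numeric vector of 20 features.
#' @export
first_order_features <- function(vol, mask, n_bins = 64) {
  assert_that(inherits(vol, "image_volume"), "vol must be an image_volume")
  check_mask_matches(vol, mask)
  x <- vol$data[mask$voxels]
  assert_that(length(x) >= 2, "mask must contain at least 2 voxels")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  v <- var(x)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  p <- hist_probs(x, n_bins)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  c(mean = mu, median = q[3], min = min(x), max = max(x),
    range = max(x) - min(x), variance = v, sd = sqrt(v),
    skewness = skew, kurtosis = kurt,
    energy = sum(x^2), entropy = entropy_bits(p),
    p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
    iqr = q[4] - q[2],
    mad_mean = mean(abs(x - mu)), mad_median = median(abs(x - q[3])),
    cv = if (abs(mu) > 0) sqrt(v) / mu else NA_real_,
    uniformity = sum(p^2))
}

hist_probs <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(1)
  width <- (hi - lo) / n_bins
  b <- pmin(floor((x - lo) / width) + 1, n_bins)
  tabulate(b, n_bins) / length(x)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
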