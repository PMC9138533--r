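# Shared fixtures and independent brute-force oracles.

# tiny CT volume with a bright body slab and a mid-intensity insert
make_toy_ct <- function(level = 1000, dims = c(12, 12, 8)) {
  arr <- array(0, dims)
  arr[2:11, 2:11, 2:7] <- 2400                       # "body"
  arr[4:9, 4:9, 3:6] <- level                        # "lung"
  image_volume(arr, c(0.4, 0.4, 0.6), "CT", "offset-HU")
}

toy_mask <- function(vol, predicate) {
  roi_mask(array(predicate(vol$data), dim(vol$data)), vol$spacing)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

all_26_offsets <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(o[rowSums(abs(o)) > 0, ])
}

# Exhaustive pair-enumeration oracle for the co-occurrence matrix: walks
# every voxel and every (unsigned-direction, distance) offset in both
# senses, counting level pairs where both ends are masked.
bf_glcm <- function(lev, ng, distance = 1) {
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  offs <- all_26_offsets()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offs))) {
      p <- c(x, y, z) + distance * offs[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- lev[p[1], p[2], p[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# Exhaustive collinear-triplet oracle with reversal symmetrization.
bf_triplet <- function(lev, ng, distance = 1) {
  d <- dim(lev)
  counts <- array(0, c(ng, ng, ng))
  offs <- all_26_offsets()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offs))) {
      p1 <- c(x, y, z) + distance * offs[r, ]
      p2 <- c(x, y, z) + 2 * distance * offs[r, ]
      if (any(p1 < 1) || any(p1 > d) || any(p2 < 1) || any(p2 > d)) next
      b <- lev[p1[1], p1[2], p1[3]]
      cc <- lev[p2[1], p2[2], p2[3]]
      if (is.na(b) || is.na(cc)) next
      counts[a, b, cc] <- counts[a, b, cc] + 1
    }
  }
  counts / sum(counts)
}

# Rank-statistic (Mann-Whitney) AUC with ties counted one half.
rank_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random quantized ROI on a small grid, some voxels masked out
random_quantized <- function(dims = c(4, 4, 3), ng = 4, p_mask = 0.8) {
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  lev[runif(prod(dims)) > p_mask] <- NA_integer_
  structure(list(levels = lev, n_levels = as.integer(ng),
                 bin_edges = 0:ng, spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

# 1D row embedded in a 3D grid, quantized as given
row_quantized <- function(levels, ng) {
  lev <- array(NA_integer_, c(length(levels), 1, 1))
  lev[, 1, 1] <- as.integer(levels)
  structure(list(levels = lev, n_levels = as.integer(ng),
                 bin_edges = 0:ng, spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

# small fast phantom spec for pipeline-level tests
small_ct_spec <- function(seed = NULL)
  phantom_spec("CT", grid_shape = c(32, 32, 24), spacing_mm = c(0.4, 0.4, 0.6),
               lung_centers_mm = rbind(c(4.3, 6.4, 7.2), c(8.5, 6.4, 7.2)),
               lung_semiaxes_mm = rbind(c(1.6, 2, 3), c(1.6, 2, 3)),
               seed = seed)

small_mri_spec <- function(seed = NULL)
  phantom_spec("MRI", grid_shape = c(26, 26, 24), spacing_mm = c(0.5, 0.5, 0.5),
               lung_centers_mm = rbind(c(4.3, 6.5, 6), c(8.5, 6.5, 6)),
               lung_semiaxes_mm = rbind(c(1.6, 2, 3), c(1.6, 2, 3)),
               seed = seed)
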