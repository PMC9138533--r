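# Second-order (pair) and third-order (collinear triplet) joint
# probability texture structures over a quantized region of interest.
#
# Pairs/triplets are taken along the 13 unique 3D lattice directions at a
# fixed voxel distance, pooled into a single matrix/tensor, symmetrized
# (pairs: P = t(P); triplets: reversal T[i,j,k] = T[k,j,i]) and normalized
# to sum 1.  Offsets are lattice steps, not mm-isotropic, so anisotropic
# spacing is used as-is.

# voxel pairs (src, dst) at offset o (in voxels) where both ends are masked;
# returns their quantized levels.
masked_pairs <- function(lev, o) {
  d <- dim(lev)
  rx <- pair_range(d[1], o[1]); ry <- pair_range(d[2], o[2])
  rz <- pair_range(d[3], o[3])
  if (!length(rx$src) || !length(ry$src) || !length(rz$src))
    return(list(a = integer(0), b = integer(0)))
  a <- lev[rx$src, ry$src, rz$src]
  b <- lev[rx$dst, ry$dst, rz$dst]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

pair_range <- function(n, o) {
  if (o >= 0) {
    if (o >= n) return(list(src = integer(0), dst = integer(0)))
    list(src = seq_len(n - o), dst = seq_len(n - o) + o)
  } else {
    if (-o >= n) return(list(src = integer(0), dst = integer(0)))
    list(src = seq_len(n + o) - o, dst = seq_len(n + o))
  }
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized levels over all masked voxel pairs
#' separated by `distance` lattice steps along each direction of
#' `direction_set`, symmetrizes, pools the directions into one matrix and
#' normalizes it to total probability 1.
#'
#' @param q A [quantize]d region of interest.
#' @param distance Offset length in voxels (>= 1).
#' @param direction_set Integer matrix of offsets (rows), by default the 13
#'   unique 3D directions.
#' @return An object of class `glcm`: probability matrix `P` (Ng x Ng),
#'   `distance`, `direction_set`, `n_levels`, `n_pairs`.
#' @export
build_glcm <- function(q, distance = 1, direction_set = unique_offsets_3d()) {
  assert_that(inherits(q, "quantized_roi"), "q must be a quantized_roi")
  assert_that(distance >= 1, "distance must be >= 1")
  ng <- q$n_levels
  counts <- matrix(0, ng, ng)
  total <- 0L
  for (k in seq_len(nrow(direction_set))) {
    pr <- masked_pairs(q$levels, distance * direction_set[k, ])
    if (!length(pr$a)) next
    cm <- matrix(tabulate((pr$a - 1L) * ng + pr$b, ng * ng), ng, ng)
    counts <- counts + cm + t(cm)
    total <- total + 2L * length(pr$a)
  }
  assert_that(total > 0, "mask admits no voxel pairs at this offset")
  structure(list(P = counts / total, distance = distance,
                 direction_set = direction_set, n_levels = ng,
                 n_pairs = total),
            class = "glcm")
}

#' Features of a gray-level co-occurrence matrix
#'
#' Fourteen second-order texture features: entropy (bits; with 64 levels it
#' is bounded by 12), energy, contrast, correlation, homogeneity (inverse
#' difference), dissimilarity, cluster shade, cluster prominence, maximum
#' probability, sum average, sum entropy, difference entropy,
#' autocorrelation, and IMC1-style normalized entropy.
#'
#' @param g A `glcm` (or a bare normalized matrix).
#' @return Named numeric vector of 14 features.
#' @export
glcm_features <- function(g) {
  P <- if (inherits(g, "glcm")) g$P else as.matrix(g)
  assert_that(abs(sum(P) - 1) < 1e-6, "co-occurrence matrix must sum to 1")
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  ent <- entropy_bits(P)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0

  # sum / difference marginals
  psum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  pdiff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))

  hx <- entropy_bits(px); hy <- entropy_bits(py)
  pij <- outer(px, py)
  hxy1 <- -sum(P[pij > 0] * log2(pij[pij > 0]))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0

  c(entropy = ent,
    energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    homogeneity = sum(P / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    max_probability = max(P),
    sum_average = sum((2:(2 * ng)) * psum),
    sum_entropy = entropy_bits(psum),
    difference_entropy = entropy_bits(pdiff),
    autocorrelation = sum(i * j * P),
    imc1 = imc1)
}

#' Third-order collinear-triplet co-occurrence tensor
#'
#' Counts quantized level triples over collinear masked voxel triplets
#' (v, v + d u, v + 2 d u) for each direction u, symmetrizes under reversal
#' (`T[i,j,k] = T[k,j,i]`) and normalizes to sum 1.
#'
#' @inheritParams build_glcm
#' @return An object of class `triplet_cooc`: array `T` (Ng^3), `distance`,
#'   `direction_set`, `n_levels`, `n_triplets`.
#' @export
build_triplet_cooccurrence <- function(q, distance = 1,
                                       direction_set = unique_offsets_3d()) {
  assert_that(inherits(q, "quantized_roi"), "q must be a quantized_roi")
  assert_that(distance >= 1, "distance must be >= 1")
  ng <- q$n_levels
  counts <- numeric(ng^3)
  total <- 0L
  d <- dim(q$levels)
  for (k in seq_len(nrow(direction_set))) {
    o <- distance * direction_set[k, ]
    rx <- triple_range(d[1], o[1]); ry <- triple_range(d[2], o[2])
    rz <- triple_range(d[3], o[3])
    if (!length(rx$a) || !length(ry$a) || !length(rz$a)) next
    a <- q$levels[rx$a, ry$a, rz$a]
    b <- q$levels[rx$b, ry$b, rz$b]
    cc <- q$levels[rx$c, ry$c, rz$c]
    ok <- !is.na(a) & !is.na(b) & !is.na(cc)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]; cc <- cc[ok]
    idx <- (a - 1L) * ng * ng + (b - 1L) * ng + cc
    ridx <- (cc - 1L) * ng * ng + (b - 1L) * ng + a
    counts <- counts + tabulate(idx, ng^3) + tabulate(ridx, ng^3)
    total <- total + 2L * length(a)
  }
  assert_that(total > 0, "mask admits no collinear triplets at this offset")
  structure(list(T = array(counts / total, c(ng, ng, ng)),
                 distance = distance, direction_set = direction_set,
                 n_levels = ng, n_triplets = total),
            class = "triplet_cooc")
}

triple_range <- function(n, o) {
  lo <- min(0, o, 2 * o); hi <- max(0, o, 2 * o)
  len <- n - (hi - lo)
  if (len < 1) return(list(a = integer(0), b = integer(0), c = integer(0)))
  start <- 1 - lo
  list(a = start:(start + len - 1),
       b = start:(start + len - 1) + o,
       c = start:(start + len - 1) + 2 * o)
}

#' Features of a triplet co-occurrence tensor
#'
#' Six third-order texture features: entropy (bits), energy, contrast
#' (`sum T (|i-j| + |j-k|)^2 / 4`), homogeneity
#' (`sum T / (1 + (|i-j| + |j-k|)/2)`), maximum probability and cluster
#' tendency (`sum T (i+j+k - 3 mu)^2`).
#'
#' @param t3 A `triplet_cooc` (or a bare normalized Ng^3 array).
#' @return Named numeric vector of 6 features.
#' @export
triplet_features <- function(t3) {
  T <- if (inherits(t3, "triplet_cooc")) t3$T else as.array(t3)
  assert_that(abs(sum(T) - 1) < 1e-6, "triplet tensor must sum to 1")
  ng <- dim(T)[1]
  i <- slice.index(T, 1); j <- slice.index(T, 2); k <- slice.index(T, 3)
  pm <- (apply(T, 1, sum) + apply(T, 2, sum) + apply(T, 3, sum)) / 3
  mu <- sum(seq_len(ng) * pm)
  spread <- abs(i - j) + abs(j - k)
  c(entropy = entropy_bits(T),
    energy = sum(T^2),
    contrast = sum(T * spread^2) / 4,
    homogeneity = sum(T / (1 + spread / 2)),
    max_probability = max(T),
    cluster_tendency = sum(T * (i + j + k - 3 * mu)^2))
}
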