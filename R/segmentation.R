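# Threshold-based CT lung segmentation.
#
# The published procedure is semi-automatic: window the CT between the two
# lung threshold levels, review, and manually strip the trachea.  Here the
# window is applied inside the body region (bounding box of the largest
# bright connected component), small components are removed, and a
# deterministic trachea proxy drops midline tube-like components.

# 13 unique 3D lattice offsets (26-connectivity up to sign).
unique_offsets_3d <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  keep <- apply(o, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(o[keep, , drop = FALSE])
}

# Connected-component labelling of a logical 3D array (26-neighbourhood).
# Returns an integer array of labels (0 = background), labelled in
# decreasing size order so label 1 is always the largest component.
label_components <- function(fg, connectivity = 26) {
  assert_that(connectivity == 26, "only 26-connectivity is implemented")
  dims <- dim(fg)
  idx <- which(fg)
  lab <- array(0L, dims)
  if (!length(idx)) return(lab)
  id <- integer(prod(dims))
  id[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  edges <- vector("list", 13)
  offs <- unique_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ok <- coords[, 1] + o[1] >= 1 & coords[, 1] + o[1] <= dims[1] &
          coords[, 2] + o[2] >= 1 & coords[, 2] + o[2] <= dims[2] &
          coords[, 3] + o[3] >= 1 & coords[, 3] + o[3] <= dims[3]
    nb <- idx[ok] + sum(o * strides)
    hit <- fg[nb]
    edges[[k]] <- cbind(id[idx[ok][hit]], id[nb[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  ord <- order(tabulate(memb), decreasing = TRUE)
  relab <- integer(max(memb))
  relab[ord] <- seq_along(ord)
  lab[idx] <- relab[memb]
  lab
}

component_stats <- function(lab, label, spacing) {
  idx <- which(lab == label)
  coords <- arrayInd(idx, dim(lab))
  xyz <- sweep(coords, 2, spacing, `*`)
  n <- nrow(xyz)
  centroid_frac_x <- (mean(coords[, 1]) - 0.5) / dim(lab)[1]
  elong <- if (n >= 3) {
    ev <- eigen(cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    if (ev[2] <= .Machine$double.eps * ev[1]) Inf else sqrt(ev[1] / ev[2])
  } else Inf
  list(size = n, elongation = elong, centroid_frac_x = centroid_frac_x)
}

#' Segment lungs on CT by intensity thresholding
#'
#' Voxels with `low_thresh <= intensity <= high_thresh` are kept, restricted
#' to the bounding box of the largest bright (`> high_thresh`) component
#' (body interior), cleaned by dropping 26-connected components smaller than
#' `min_component_voxels`, and finally filtered by a trachea proxy: any
#' component whose principal-axis elongation exceeds 4 while its centroid
#' lies within the central 20% of the left-right axis is removed. The
#' default 800--1200 window assumes an air-near-zero offset intensity scale
#' (see [image_volume]); pass other thresholds for standard HU data.
#'
#' @param vol A CT [image_volume].
#' @param low_thresh,high_thresh Inclusive intensity window,
#'   `low_thresh < high_thresh`.
#' @param min_component_voxels Drop accepted components smaller than this.
#' @param keep_all_components Disable the trachea-proxy removal.
#' @return An [roi_mask]; errors if no voxels survive filtering.
#' @export
segment_lungs_ct <- function(vol, low_thresh = 800, high_thresh = 1200,
                             min_component_voxels = 50,
                             keep_all_components = FALSE) {
  assert_that(inherits(vol, "image_volume"), "vol must be an image_volume")
  assert_that(identical(vol$modality, "CT"), "threshold segmentation is CT-only")
  assert_that(low_thresh < high_thresh, "low_thresh must be below high_thresh")
  x <- vol$data
  win <- x >= low_thresh & x <= high_thresh

  bright <- x > high_thresh
  if (any(bright)) {
    blab <- label_components(bright)
    body <- blab == 1L
    rng <- apply(arrayInd(which(body), dim(x)), 2, range)
    box <- array(FALSE, dim(x))
    box[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3]] <- TRUE
    win <- win & box
  }
  if (!any(win)) stop_pr("segmentation produced an empty mask")

  lab <- label_components(win)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_voxels)
  if (!keep_all_components) {
    keep <- keep[vapply(keep, function(k) {
      st <- component_stats(lab, k, vol$spacing)
      !(st$elongation > 4 && abs(st$centroid_frac_x - 0.5) <= 0.1)
    }, logical(1))]
  }
  if (!length(keep)) stop_pr("segmentation produced an empty mask after filtering")
  roi_mask(array(lab %in% keep, dim(x)), vol$spacing)
}
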