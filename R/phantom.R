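# Textured two-lung imaging phantoms.
#
# The phantom is two ellipsoidal "lungs" inside a bright soft-tissue body
# ellipsoid on an air background, at the acquisition spacings of the study
# (CT 0.4 x 0.4 x 0.6 mm, MRI 0.5 mm isotropic).  Lung texture is
# group-dependent: a smoothed (spatially correlated) Gaussian field plus an
# independent two-component scale-mixture noise whose wide/narrow sd ratio
# steers histogram kurtosis monotonically (tail weight fixed at 0.05; the
# ratio 1 gives an ordinary normal, kurtosis 3).

#' Specification of a two-lung imaging phantom
#'
#' Defaults give bilateral ellipsoidal lungs of about 821 mm^3 combined
#' (semi-axes 3.5 x 4 x 7 mm, matching the study's mean bilateral lung
#' volume of 823.5 mm^3 to within discretization), fully inside the grid.
#'
#' @param modality `"CT"` or `"MRI"`; selects default grid, spacing and
#'   intensity levels.
#' @param grid_shape Integer length-3 voxel counts.
#' @param spacing_mm Voxel spacing in mm (CT default 0.4 x 0.4 x 0.6,
#'   MRI default 0.5 isotropic).
#' @param lung_centers_mm 2 x 3 matrix of ellipsoid centers in mm.
#' @param lung_semiaxes_mm 2 x 3 matrix of semi-axes in mm.
#' @param background_level,lung_level,body_level Base intensities (CT on the
#'   air-near-zero offset scale so the 800--1200 lung window applies).
#' @param body_margin_mm Margin of the body ellipsoid around the lungs.
#' @param bg_noise_sd Gaussian noise sd outside the lungs.
#' @param texture_params Per-group list (`low`, `high`) of `noise_sd`,
#'   `smooth_mm` (correlation length of the smoothed field), `shape`
#'   (scale-mixture sd ratio >= 1 controlling kurtosis) and `level_shift`
#'   (additive offset to `lung_level`).
#' @param seed Integer RNG seed or `NULL`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(modality = c("CT", "MRI"),
                         grid_shape = NULL, spacing_mm = NULL,
                         lung_centers_mm = NULL, lung_semiaxes_mm = NULL,
                         background_level = NULL, lung_level = NULL,
                         body_level = NULL, body_margin_mm = 1.5,
                         bg_noise_sd = 10,
                         texture_params = NULL, seed = NULL) {
  modality <- match.arg(modality)
  if (is.null(grid_shape))
    grid_shape <- if (modality == "CT") c(64L, 64L, 40L) else c(52L, 52L, 48L)
  if (is.null(spacing_mm))
    spacing_mm <- if (modality == "CT") c(0.4, 0.4, 0.6) else c(0.5, 0.5, 0.5)
  extent <- grid_shape * spacing_mm
  if (is.null(lung_centers_mm))
    lung_centers_mm <- rbind(extent / 2 + c(-5.5, 0, 0),
                             extent / 2 + c(5.5, 0, 0))
  if (is.null(lung_semiaxes_mm))
    lung_semiaxes_mm <- rbind(c(3.5, 4, 7), c(3.5, 4, 7))
  if (is.null(background_level))
    background_level <- if (modality == "CT") 0 else 10
  if (is.null(lung_level))
    lung_level <- if (modality == "CT") 1000 else 400
  if (is.null(body_level))
    body_level <- if (modality == "CT") 2400 else 700
  if (is.null(texture_params)) {
    noise <- if (modality == "CT") 60 else 40
    texture_params <- if (modality == "CT")
      list(low  = list(noise_sd = noise, smooth_mm = 0.8, shape = 1.0,
                       level_shift = 0),
           high = list(noise_sd = noise, smooth_mm = 1.2, shape = 1.8,
                       level_shift = 12))
    else
      list(low  = list(noise_sd = noise, smooth_mm = 0.8, shape = 2.8,
                       level_shift = 0),
           high = list(noise_sd = noise, smooth_mm = 1.2, shape = 1.4,
                       level_shift = 0))
  }
  spacing_mm <- as.numeric(spacing_mm)
  assert_that(all(spacing_mm > 0), "spacing must be strictly positive")
  lung_centers_mm <- as.matrix(lung_centers_mm)
  lung_semiaxes_mm <- as.matrix(lung_semiaxes_mm)
  assert_that(all(lung_semiaxes_mm > 0), "semi-axes must be positive")
  for (e in seq_len(nrow(lung_centers_mm))) {
    lo <- lung_centers_mm[e, ] - lung_semiaxes_mm[e, ]
    hi <- lung_centers_mm[e, ] + lung_semiaxes_mm[e, ]
    assert_that(all(lo >= 0) && all(hi <= extent),
                "lung ellipsoid extends outside the grid")
  }
  for (g in c("low", "high"))
    assert_that(texture_params[[g]]$shape >= 1,
                "texture shape (sd ratio) must be >= 1")
  structure(list(modality = modality, grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm,
                 lung_centers_mm = lung_centers_mm,
                 lung_semiaxes_mm = lung_semiaxes_mm,
                 background_level = background_level,
                 lung_level = lung_level, body_level = body_level,
                 body_margin_mm = body_margin_mm, bg_noise_sd = bg_noise_sd,
                 texture_params = texture_params, seed = seed),
            class = "phantom_spec")
}

# Voxel-center coordinate arrays (mm) for a grid.
voxel_centers <- function(grid_shape, spacing_mm) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing_mm[a])
}

# Voxelized ellipsoid predicate over voxel centers.
ellipsoid_mask <- function(grid_shape, spacing_mm, center, semiaxes) {
  cc <- voxel_centers(grid_shape, spacing_mm)
  u2 <- lapply(1:3, function(a) ((cc[[a]] - center[a]) / semiaxes[a])^2)
  d2 <- outer(outer(u2[[1]], u2[[2]], `+`), u2[[3]], `+`)
  array(d2 <= 1, grid_shape)
}

# Ground-truth lung mask implied by a phantom spec (no RNG involved).
phantom_lung_mask <- function(spec) {
  m <- ellipsoid_mask(spec$grid_shape, spec$spacing_mm,
                      spec$lung_centers_mm[1, ], spec$lung_semiaxes_mm[1, ])
  for (e in seq_len(nrow(spec$lung_centers_mm))[-1])
    m <- m | ellipsoid_mask(spec$grid_shape, spec$spacing_mm,
                            spec$lung_centers_mm[e, ],
                            spec$lung_semiaxes_mm[e, ])
  m
}

# FFT-based separable Gaussian smoothing of a 3D array (periodic boundary).
gaussian_blur_fft <- function(x, sigma_vox) {
  d <- dim(x)
  att <- lapply(1:3, function(a) {
    f <- (seq_len(d[a]) - 1) / d[a]
    f <- ifelse(f > 0.5, f - 1, f)
    exp(-2 * pi^2 * sigma_vox[a]^2 * f^2)
  })
  g <- outer(outer(att[[1]], att[[2]]), att[[3]])
  Re(fft(fft(x) * g, inverse = TRUE)) / length(x)
}

#' Generate a textured two-lung phantom
#'
#' Builds the volume and its exact ground-truth lung mask. Voxels inside the
#' lungs carry `lung_level + level_shift` plus a correlated Gaussian field
#' (sd `0.5 * noise_sd`, correlation length `smooth_mm`) and a scale-mixture
#' noise (sd `noise_sd`, tail weight 0.05, wide/narrow sd ratio `shape`);
#' body voxels sit at `body_level` and background at `background_level`,
#' each with N(0, `bg_noise_sd`) noise. With the same seed the two groups
#' share the underlying random fields, so masks are identical and only the
#' texture transform differs.
#'
#' @param spec A [phantom_spec].
#' @param group `"low"` or `"high"` inflammation texture group.
#' @return A list with elements `volume` ([image_volume]) and `mask`
#'   ([roi_mask]).
#' @export
generate_phantom <- function(spec, group = c("low", "high")) {
  group <- match.arg(group)
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  tp <- spec$texture_params[[group]]
  d <- spec$grid_shape
  lung <- phantom_lung_mask(spec)
  body_semi <- apply(abs(sweep(spec$lung_centers_mm, 2,
                               d * spec$spacing_mm / 2)) +
                     spec$lung_semiaxes_mm, 2, max) + spec$body_margin_mm
  body <- ellipsoid_mask(d, spec$spacing_mm, d * spec$spacing_mm / 2,
                         body_semi)

  with_seed(spec$seed, {
    white <- array(rnorm(prod(d)), d)       # shared field, blurred per group
    eps <- rnorm(sum(lung))                 # scale-mixture innovations
    wide <- runif(sum(lung)) < 0.05
    bg_noise <- rnorm(prod(d), 0, spec$bg_noise_sd)

    smooth <- gaussian_blur_fft(white, tp$smooth_mm / spec$spacing_mm)
    sm_lung <- smooth[lung]
    sm_lung <- (sm_lung - mean(sm_lung)) / max(sd(sm_lung), 1e-12)

    vol <- array(spec$background_level, d) + bg_noise
    vol[body] <- spec$body_level + bg_noise[body]
    vol[lung] <- spec$lung_level + tp$level_shift +
      0.5 * tp$noise_sd * sm_lung +
      tp$noise_sd * eps * ifelse(wide, tp$shape, 1)

    list(volume = image_volume(vol, spec$spacing_mm, spec$modality,
                               if (spec$modality == "CT") "offset-HU" else "raw"),
         mask = roi_mask(lung, spec$spacing_mm))
  })
}

#' Generate a full synthetic imaging cohort on disk
#'
#' Writes, for every subject of a tabular cohort, a CT and an MRI phantom
#' whose texture group matches the subject's CD45 group, together with the
#' ground-truth lung masks (NIfTI) and the cohort table (CSV). Per-subject
#' phantom seeds are derived deterministically from the cohort seed, so
#' repeated runs are byte-identical.
#'
#' @param spec A [cohort_spec].
#' @param ct_spec,mri_spec [phantom_spec]s for the two modalities.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the cohort data frame and a file manifest
#'   data frame (`subject_id`, `modality`, `volume`, `mask`).
#' @export
generate_imaging_cohort <- function(spec, ct_spec = phantom_spec("CT"),
                                    mri_spec = phantom_spec("MRI"),
                                    out_dir) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), paste0("cannot create directory ", out_dir))
  cohort <- generate_tabular_cohort(spec)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$group[i]
    for (m in c("ct", "mri")) {
      ps <- if (m == "ct") ct_spec else mri_spec
      ps$seed <- child_seed(spec$seed %||% 0, 2L * i + (m == "mri"))
      ph <- generate_phantom(ps, g)
      vf <- file.path(out_dir, sprintf("%s_%s.nii.gz", cohort$subject_id[i], m))
      mf <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz",
                                       cohort$subject_id[i], m))
      write_volume(ph$volume, vf)
      write_mask(ph$mask, mf)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = cohort$subject_id[i],
                   modality = toupper(m), volume = vf, mask = mf,
                   stringsAsFactors = FALSE)
    }
  }
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(cohort = cohort, manifest = manifest, dir = out_dir))
}
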