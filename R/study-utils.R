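# Closed-form design calculations used for experiment sanity checks.

#' Caliper tumor volume
#'
#' Ellipsoid approximation from two caliper measurements:
#' `width^2 * length / 2` (mm^3).
#'
#' @param width_mm,length_mm Non-negative caliper measurements in mm.
#' @return Volume in mm^3.
#' @export
tumor_volume_mm3 <- function(width_mm, length_mm) {
  assert_that(all(width_mm >= 0) && all(length_mm >= 0),
              "caliper measurements must be non-negative")
  width_mm^2 * length_mm / 2
}

#' X-ray transmission through a lead shield
#'
#' Pure exponential attenuation: `0.5^(thickness / hvl)`. With the
#' half-value layer of Pb at 160 kVp of about 0.3 mm, a 2.0 mm shield
#' transmits just under 1% of the beam.
#'
#' @param thickness_mm Shield thickness in mm (>= 0).
#' @param half_value_layer_mm Half-value layer in mm (> 0; default 0.3, Pb
#'   at 160 kVp).
#' @return Transmitted fraction in (0, 1].
#' @export
shield_transmission <- function(thickness_mm, half_value_layer_mm = 0.3) {
  assert_that(all(thickness_mm >= 0), "thickness must be non-negative")
  assert_that(all(half_value_layer_mm > 0), "half-value layer must be positive")
  0.5^(thickness_mm / half_value_layer_mm)
}
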