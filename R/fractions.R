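# Simulated multi-fraction series: anatomical change across fractions is
# emulated by interpolating one displacement field between its negation and
# itself, and applying each scaled field to both the base image (trilinear)
# and its contours (nearest-neighbour).

#' Scale a displacement field
#'
#' Multiplies every displacement vector by `s`. Negation is a literal sign
#' flip of the field, not a true inverse deformation; the interpolation
#' between `-DVF` and `+DVF` used for fraction simulation is defined in
#' terms of this literal scaling.
#'
#' @param dvf a [displacement_field()].
#' @param s finite scalar.
#' @return A [displacement_field()].
#' @export
scale_dvf <- function(dvf, s) {
  stopifnot(inherits(dvf, "displacement_field"), is.finite(s))
  displacement_field(dvf$vectors * s)
}

#' Simulate the fractions of one patient from a single displacement field
#'
#' For each scale `s` the field `s * dvf` is applied to the base image
#' (trilinear) and to every contour (nearest-neighbour), producing one
#' simulated fraction per scale in list order. The default scales
#' `c(-1, -0.5, 0, 0.5, 1)` yield five fractions; the `s = 0` fraction is
#' bit-identical to the base image and contours.
#'
#' @param base_image an [image_volume()] (the fraction-imaging role).
#' @param base_contours a [structure_set()] on the same grid.
#' @param dvf a [displacement_field()] on the same grid.
#' @param scales numeric vector of interpolation factors; must be nonempty.
#' @param patient_id identifier stored on the series.
#' @param planning_image,planning_contours the planning-role image and
#'   contours placed at the head of the series; default to the base pair.
#' @return A [patient_series()] with one simulated fraction per scale.
#' @export
simulate_fractions <- function(base_image, base_contours, dvf,
                               scales = c(-1, -0.5, 0, 0.5, 1),
                               patient_id = "sim",
                               planning_image = base_image,
                               planning_contours = base_contours) {
  stopifnot(inherits(base_image, "image_volume"),
            inherits(base_contours, "structure_set"),
            inherits(dvf, "displacement_field"))
  if (length(scales) < 1L)
    stop("at least one scale is required", call. = FALSE)
  fractions <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    if (s == 0) {
      img <- base_image
      ctr <- base_contours
    } else {
      sdvf <- scale_dvf(dvf, s)
      img <- warp_image(base_image, sdvf)
      ctr <- warp_structure_set(base_contours, sdvf)
    }
    fractions[[i]] <- fraction_record(i, img, ctr, provenance = "simulated")
  }
  patient_series(patient_id, planning_image, planning_contours, fractions)
}

#' Build a simulated pre-training cohort
#'
#' Generates `n_patients` independent phantoms and displacement fields from
#' seed-derived sub-seeds and expands each into a multi-fraction series via
#' [simulate_fractions()].
#'
#' @param n_patients number of patients (>= 1).
#' @param config a [phantom_config()]; its `dvf_amplitude`/`dvf_smoothness`
#'   control the per-patient field.
#' @param scales interpolation factors passed to [simulate_fractions()].
#' @param seed master seed; per-patient seeds are derived from it.
#' @return A list of [patient_series()].
#' @export
build_pretrain_cohort <- function(n_patients, config = phantom_config(),
                                  scales = c(-1, -0.5, 0, 0.5, 1),
                                  seed = 1L) {
  stopifnot(n_patients >= 1L)
  sub <- derive_seeds(seed, 2L * n_patients)
  lapply(seq_len(n_patients), function(p) {
    cfg <- config
    cfg$seed <- sub[2L * p - 1L]
    ph <- make_phantom(cfg)
    dvf <- make_smooth_dvf(cfg$shape, cfg$dvf_amplitude, cfg$dvf_smoothness,
                           seed = sub[2L * p])
    simulate_fractions(ph$image, ph$contours, dvf, scales = scales,
                       patient_id = sprintf("sim_%03d", p))
  })
}
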