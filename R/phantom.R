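# Synthetic deformable phantoms: multi-organ volumes plus smooth random
# displacement fields, so the whole adaptive-course pipeline is exercisable
# without clinical data.

#' Phantom generation settings
#'
#' Organ intensities are drawn independently per phantom, deliberately: on
#' cone-beam images soft-tissue contrast is poor and absolute intensity does
#' not reliably identify a structure across patients, so a segmentation
#' model must rely on prior contours rather than a fixed intensity-to-organ
#' mapping. Keeping intensities patient-specific reproduces that ambiguity.
#'
#' @param shape integer length-3 grid size (each >= 8).
#' @param n_structures number of non-overlapping ellipsoidal organs (>= 1).
#' @param noise_sd additive Gaussian intensity noise (image units; the
#'   phantom emits already-normalized intensities in \[0, 1\]).
#' @param dvf_amplitude maximum displacement magnitude, voxels. The
#'   default (together with `dvf_smoothness`) is calibrated so that
#'   rigidly-propagated prior contours on consecutive simulated fractions
#'   achieve a mean Dice in the mid-0.8s — the regime reported for
#'   registration-based contour propagation on clinical serial imaging.
#'   Very smooth fields are largely absorbed by rigid alignment, so the
#'   residual deformation that matters is controlled by both parameters.
#' @param dvf_smoothness Gaussian smoothing sigma of the field, voxels.
#' @param spacing voxel size in mm.
#' @param seed RNG seed for reproducible phantoms.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32L, 32L, 32L), n_structures = 3L,
                           noise_sd = 0.03, dvf_amplitude = 10,
                           dvf_smoothness = 2, spacing = c(1, 1, 1),
                           seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_structures >= 1L,
            noise_sd >= 0, dvf_amplitude >= 0, dvf_smoothness > 0)
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 noise_sd = noise_sd, dvf_amplitude = dvf_amplitude,
                 dvf_smoothness = dvf_smoothness, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a multi-organ phantom
#'
#' Places `n_structures` ellipsoidal organs with distinct mean intensities
#' over a constant background (0.1), with at least a 2-voxel margin between
#' organs and to the volume edge, then adds Gaussian intensity noise.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return A list with `image` ([image_volume()]) and `contours`
#'   ([structure_set()], one mask per organ, named `organ_1`, ...).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$shape
  with_seed(config$seed, {
    margin <- 2
    r_lo <- 0.10 * min(shp)
    r_hi <- 0.18 * min(shp)
    centers <- list(); radii <- list()
    for (k in seq_len(config$n_structures)) {
      placed <- FALSE
      lo <- r_lo; hi <- r_hi
      # progressively shrink the radius range when a crowded volume
      # rejects too many draws; give up only when even small organs
      # (radius 1.5 voxels) cannot be placed
      while (!placed && hi >= 1.5) {
        for (try in seq_len(200L)) {
          r <- runif(3, lo, hi)
          if (any(r + margin + 1 >= shp - r - margin)) next
          ctr <- runif(3, r + margin + 1, shp - r - margin)
          ok <- TRUE
          for (j in seq_along(centers)) {
            gap <- sqrt(sum((ctr - centers[[j]])^2)) -
              max(r) - max(radii[[j]])
            if (gap < margin) { ok <- FALSE; break }
          }
          if (ok) {
            centers[[k]] <- ctr; radii[[k]] <- r; placed <- TRUE; break
          }
        }
        if (!placed) { hi <- max(hi * 0.8, 1.5); lo <- min(lo, hi * 0.7) }
      }
      if (!placed)
        stop("shape too small to place ", config$n_structures,
             " structures with a ", margin, "-voxel margin", call. = FALSE)
    }
    # organ intensities: patient-specific, pairwise separated by >= 0.05
    repeat {
      ints <- runif(config$n_structures, 0.35, 0.95)
      if (config$n_structures == 1L ||
          min(dist(ints)) >= 0.05) break
    }
    d <- seq_len(shp[1]); h <- seq_len(shp[2]); w <- seq_len(shp[3])
    img <- array(0.1, shp)
    masks <- list()
    for (k in seq_len(config$n_structures)) {
      ctr <- centers[[k]]; r <- radii[[k]]
      e <- outer(outer(((d - ctr[1]) / r[1])^2, ((h - ctr[2]) / r[2])^2, "+"),
                 ((w - ctr[3]) / r[3])^2, "+")
      m <- array(as.numeric(e <= 1), shp)
      img[m == 1] <- ints[k]
      masks[[paste0("organ_", k)]] <- m
    }
    if (config$noise_sd > 0)
      img <- img + array(rnorm(prod(shp), 0, config$noise_sd), shp)
    list(image = image_volume(img, spacing = config$spacing),
         contours = structure_set(masks))
  })
}

#' Generate a smooth random displacement field
#'
#' Per-component Gaussian white noise is smoothed with a separable Gaussian
#' kernel and globally rescaled so the maximum displacement magnitude equals
#' `amplitude` (a zero field when `amplitude = 0`).
#'
#' @param shape integer length-3 grid size.
#' @param amplitude maximum vector norm, voxels (>= 0).
#' @param smoothness Gaussian sigma, voxels (> 0).
#' @param seed RNG seed.
#' @return A [displacement_field()].
#' @export
make_smooth_dvf <- function(shape, amplitude, smoothness, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, amplitude >= 0, smoothness > 0)
  vec <- array(0, c(shape, 3L))
  if (amplitude > 0) {
    with_seed(seed, {
      for (c in 1:3)
        vec[, , , c] <- gauss_smooth3(array(rnorm(prod(shape)), shape),
                                      smoothness)
    })
    nrm <- sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)
    mx <- max(nrm)
    if (mx > 0) vec <- vec * (amplitude / mx)
  }
  displacement_field(vec)
}

#' Warp an image or a mask by a displacement field
#'
#' Backward (pull) warping: the output at voxel v samples the input at
#' v + field(v). Images use trilinear interpolation, masks nearest-neighbour
#' (so labels stay binary); out-of-grid samples take edge values. A zero
#' field returns the input exactly.
#'
#' @param img an [image_volume()].
#' @param dvf a [displacement_field()] on the same grid.
#' @return `warp_image()` returns an [image_volume()]; `warp_mask()` a
#'   binary 3D array.
#' @export
warp_image <- function(img, dvf) {
  stopifnot(inherits(img, "image_volume"), inherits(dvf, "displacement_field"))
  dm <- dim(img$data)
  if (!identical(dm, dim(dvf$vectors)[1:3]))
    stop("image and displacement field shapes differ", call. = FALSE)
  out <- cpp_warp_trilinear(img$data, dvf$vectors, dm[1], dm[2], dm[3])
  image_volume(out, spacing = img$spacing)
}

#' @rdname warp_image
#' @param mask 3D binary array.
#' @export
warp_mask <- function(mask, dvf) {
  stopifnot(inherits(dvf, "displacement_field"))
  mask <- as.array(mask)
  dm <- dim(mask)
  if (!identical(dm, dim(dvf$vectors)[1:3]))
    stop("mask and displacement field shapes differ", call. = FALSE)
  cpp_warp_nn(mask, dvf$vectors, dm[1], dm[2], dm[3])
}

#' @rdname warp_image
#' @param ss a [structure_set()].
#' @export
warp_structure_set <- function(ss, dvf) {
  stopifnot(inherits(ss, "structure_set"))
  structure_set(lapply(ss$masks, warp_mask, dvf = dvf))
}
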