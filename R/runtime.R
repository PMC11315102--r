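# Online adaptive-course inference: per-fraction rigid alignment of the
# prior, 3-channel input assembly, sequential prediction with memory carry,
# and the registration-only contour baseline.

#' Rigid transform
#'
#' A rotation plus translation in voxel units, applied with the pull
#' convention (the resampled image at v samples the moving image at
#' `R %*% v + t`). The estimator searches translations only, so `rotation`
#' is the identity unless supplied by the caller.
#'
#' @param translation numeric length-3, voxels.
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation = diag(3)) {
  rotation <- as.matrix(rotation)
  stopifnot(length(translation) == 3L, all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  structure(list(translation = as.numeric(translation), rotation = rotation),
            class = "rigid_transform")
}

# Dense displacement field equivalent to a rigid transform on a grid.
transform_to_dvf <- function(transform, shape) {
  shape <- as.integer(shape)
  vec <- array(0, c(shape, 3L))
  if (max(abs(transform$rotation - diag(3))) < 1e-12) {
    for (a in 1:3) vec[, , , a] <- transform$translation[a]
  } else {
    grid <- as.matrix(expand.grid(d = seq_len(shape[1]) - 1,
                                  h = seq_len(shape[2]) - 1,
                                  w = seq_len(shape[3]) - 1))
    disp <- grid %*% t(transform$rotation) - grid
    disp <- sweep(disp, 2L, transform$translation, `+`)
    for (a in 1:3) vec[, , , a] <- array(disp[, a], shape)
  }
  displacement_field(vec)
}

#' Apply a rigid transform to an image or mask
#'
#' @param transform a [rigid_transform()].
#' @param img an [image_volume()] (trilinear) or, for
#'   `apply_rigid_mask()`, a binary array (nearest-neighbour).
#' @return The resampled image or mask.
#' @export
apply_rigid <- function(transform, img) {
  warp_image(img, transform_to_dvf(transform, dim(img$data)))
}

#' @rdname apply_rigid
#' @param mask binary 3D array.
#' @export
apply_rigid_mask <- function(transform, mask) {
  warp_mask(mask, transform_to_dvf(transform, dim(mask)))
}

# 2x mean-pooling downsample (dims truncated to even).
downsample2 <- function(arr) {
  dm <- dim(arr) %/% 2L * 2L
  arr <- arr[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), drop = FALSE]
  a <- array(arr, c(2L, dm[1] %/% 2L, 2L, dm[2] %/% 2L, 2L, dm[3] %/% 2L))
  apply(a, c(2L, 4L, 6L), mean)
}

shift_mse <- function(moving, fixed, t) {
  dvf <- array(0, c(dim(moving), 3L))
  for (a in 1:3) dvf[, , , a] <- t[a]
  w <- cpp_warp_trilinear(moving, dvf, dim(moving)[1], dim(moving)[2],
                          dim(moving)[3])
  mean((w - fixed)^2)
}

#' Rigidly register two images
#'
#' Translation-only, coarse-to-fine search minimizing the mean squared
#' intensity difference: an exhaustive integer search on a mean-pooled
#' pyramid, refined by a +/-1-voxel search at each finer level. The
#' returned transform resamples `moving` onto `fixed`'s grid.
#'
#' @param moving,fixed [image_volume()]s with the same voxel spacing.
#' @param max_shift search bound at full resolution, voxels.
#' @return `list(transform = , resampled = , converged = )`.
#' @export
rigid_register <- function(moving, fixed, max_shift = 8) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  if (max(abs(moving$spacing - fixed$spacing)) > 1e-9)
    stop("images must share voxel spacing", call. = FALSE)
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("images must share one grid", call. = FALSE)
  pyr_m <- list(moving$data)
  pyr_f <- list(fixed$data)
  while (min(dim(pyr_m[[length(pyr_m)]])) >= 16L && length(pyr_m) < 3L) {
    pyr_m[[length(pyr_m) + 1L]] <- downsample2(pyr_m[[length(pyr_m)]])
    pyr_f[[length(pyr_f) + 1L]] <- downsample2(pyr_f[[length(pyr_f)]])
  }
  nlev <- length(pyr_m)
  r <- ceiling(max_shift / 2^(nlev - 1L))
  t_best <- c(0, 0, 0)
  for (lev in seq(nlev, 1L)) {
    m <- pyr_m[[lev]]; f <- pyr_f[[lev]]
    cand <- if (lev == nlev) {
      as.matrix(expand.grid(d = -r:r, h = -r:r, w = -r:r))
    } else {
      t_best <- t_best * 2
      sweep(as.matrix(expand.grid(d = -1:1, h = -1:1, w = -1:1)), 2L,
            t_best, `+`)
    }
    scores <- apply(cand, 1L, function(t) shift_mse(m, f, t))
    t_best <- as.numeric(cand[which.min(scores), ])
  }
  tf <- rigid_transform(translation = t_best)
  list(transform = tf, resampled = apply_rigid(tf, moving),
       converged = TRUE)
}

#' Assemble the 3-channel model input
#'
#' Channel 1 is the (aligned) prior image, channel 2 the prior contours
#' encoded as one label map (structure k of K maps to intensity `k / K`;
#' later structures overwrite earlier ones where masks overlap), channel 3
#' the current image.
#'
#' @param prior_image an [image_volume()] on the current grid.
#' @param prior_contours a [structure_set()] on the same grid.
#' @param current_image an [image_volume()].
#' @return Numeric array `c(D, H, W, 3)`.
#' @export
assemble_input <- function(prior_image, prior_contours, current_image) {
  stopifnot(inherits(prior_image, "image_volume"),
            inherits(current_image, "image_volume"),
            inherits(prior_contours, "structure_set"))
  if (!identical(dim(prior_image$data), dim(current_image$data)))
    stop("prior and current grids differ", call. = FALSE)
  stack_channels(prior_image$data, encode_contours(prior_contours,
                                                   dim(current_image$data)),
                 current_image$data)
}

# Label-map encoding of a structure set into one channel in [0, 1].
encode_contours <- function(contours, shape) {
  lab <- array(0, shape)
  K <- length(contours$masks)
  if (K == 0L) return(lab)
  for (k in seq_len(K)) {
    m <- contours$masks[[k]]
    if (!all(dim(m) == shape))
      stop("contour grid differs from image grid", call. = FALSE)
    lab[m == 1] <- k / K
  }
  lab
}

#' Assemble the input for registration-derived priors
#'
#' When the prior contours come from deformable registration onto the
#' current anatomy, the matching prior image is the current image itself,
#' so channels 1 and 3 are the same current image and channel 2 encodes
#' the deformed contours.
#'
#' @param current_image an [image_volume()].
#' @param dir_contours a [structure_set()] on the current grid.
#' @return Numeric array `c(D, H, W, 3)`.
#' @export
assemble_dir_input <- function(current_image, dir_contours) {
  assemble_input(current_image, dir_contours, current_image)
}

#' Registration-only contour baseline
#'
#' The previous fraction's contours resampled by the rigid transform
#' (nearest-neighbour) — the no-learning starting point a clinician would
#' otherwise revise.
#'
#' @param prior_contours a [structure_set()].
#' @param transform a [rigid_transform()].
#' @return A [structure_set()].
#' @export
contour_prior_baseline <- function(prior_contours, transform) {
  stopifnot(inherits(prior_contours, "structure_set"),
            inherits(transform, "rigid_transform"))
  if (max(abs(transform$translation)) == 0 &&
      max(abs(transform$rotation - diag(3))) == 0)
    return(prior_contours)
  structure_set(lapply(prior_contours$masks,
                       function(m) apply_rigid_mask(transform, m)))
}

#' Run the contour-prior baseline over a whole course
#'
#' For each fraction the previous fraction's ground-truth contours
#' (fraction 1: the planning contours) are rigidly aligned to the current
#' image and used directly as the segmentation — the no-learning baseline.
#'
#' @param series a [patient_series()].
#' @param register estimate the rigid alignment (default TRUE; with FALSE
#'   the identity transform is used).
#' @return A `course_prediction` with variant label `"contour_prior"`.
#' @export
contour_prior_course <- function(series, register = TRUE) {
  stopifnot(inherits(series, "patient_series"))
  n <- length(series$fractions)
  records <- vector("list", n)
  for (k in seq_len(n)) {
    cur <- series$fractions[[k]]
    prior_img <- if (k == 1L) series$planning_image
      else series$fractions[[k - 1L]]$image
    prior_ctr <- if (k == 1L) series$planning_contours
      else series$fractions[[k - 1L]]$contours
    tf <- if (register) rigid_register(prior_img, cur$image)$transform
      else rigid_transform()
    records[[k]] <- list(index = cur$index,
                         masks = contour_prior_baseline(prior_ctr, tf),
                         probs = NULL, prior_source = "previous_fraction",
                         memory = NULL)
  }
  structure(list(patient_id = series$patient_id, prior_mode = "revised",
                 variant = "contour_prior", fractions = records),
            class = "course_prediction")
}

#' Predict a whole adaptive course
#'
#' Memory starts at zero. Fraction 1 uses the planning image and contours
#' as prior; for fraction k > 1 the prior is fraction k-1's image together
#' with (mode `"revised"`, the default) its ground-truth contours — the
#' clinical situation where every past fraction was clinician-approved —
#' or (mode `"auto"`) the model's own previous prediction, or (mode
#' `"dir"`) externally deformed contours on the current grid via
#' [assemble_dir_input()]. The prior is rigidly aligned to the current
#' image before assembly; memory is updated and carried across fractions;
#' probabilities are binarized at 0.5.
#'
#' @param model a trained `progseg_model`.
#' @param series a [patient_series()].
#' @param prior_mode `"revised"`, `"auto"`, or `"dir"`.
#' @param dir_contours for `"dir"` mode: a list (one [structure_set()] per
#'   fraction) of registration-deformed contours on each fraction's grid.
#'   Defaults to each fraction's own ground truth, i.e. a perfect
#'   registration oracle; pass noise-corrupted sets to study degraded
#'   registration.
#' @param register run the rigid pre-alignment of the prior (default TRUE).
#' @param threshold binarization threshold for the predicted masks.
#' @param store_memory keep a snapshot of the memory entering each
#'   fraction in the result.
#' @return An object of class `course_prediction`: per fraction, the
#'   binarized predicted [structure_set()], the probability array, and the
#'   prior source; plus the model variant label.
#' @export
run_course <- function(model, series,
                       prior_mode = c("revised", "auto", "dir"),
                       dir_contours = NULL, register = TRUE,
                       threshold = 0.5, store_memory = FALSE) {
  stopifnot(inherits(model, "progseg_model"),
            inherits(series, "patient_series"))
  prior_mode <- match.arg(prior_mode)
  n <- length(series$fractions)
  snames <- names(series$planning_contours$masks)
  if (length(snames) != model$config$out_channels)
    stop("model output channels (", model$config$out_channels,
         ") do not match structure count (", length(snames), ")",
         call. = FALSE)
  if (prior_mode == "dir" && is.null(dir_contours))
    dir_contours <- lapply(series$fractions, function(f) f$contours)
  is_lstm <- model$config$variant == "lstm_unet"
  mem <- if (is_lstm) init_memory(model$config,
                                  dim(series$planning_image$data))
  records <- vector("list", n)
  prev_pred <- NULL
  for (k in seq_len(n)) {
    cur <- series$fractions[[k]]
    if (model$config$variant == "unet_ds") {
      input <- stack_channels(cur$image$data)
      prior_source <- "none"
    } else if (prior_mode == "dir") {
      input <- assemble_dir_input(cur$image, dir_contours[[k]])
      prior_source <- "dir_deformed"
    } else {
      if (k == 1L) {
        prior_img <- series$planning_image
        prior_ctr <- series$planning_contours
        prior_source <- "planning"
      } else {
        prior_img <- series$fractions[[k - 1L]]$image
        prior_ctr <- if (prior_mode == "revised")
          series$fractions[[k - 1L]]$contours else prev_pred
        prior_source <- "previous_fraction"
      }
      if (register) {
        reg <- rigid_register(prior_img, cur$image)
        prior_img <- reg$resampled
        prior_ctr <- contour_prior_baseline(prior_ctr, reg$transform)
      }
      input <- assemble_input(prior_img, prior_ctr, cur$image)
    }
    mem_in <- mem
    out <- model_forward(model, input, mem)
    if (is_lstm) mem <- out$memory
    masks <- lapply(seq_along(snames), function(c)
      array(as.numeric(out$probs[, , , c] >= threshold),
            dim(out$probs)[1:3]))
    names(masks) <- snames
    pred_set <- structure_set(masks)
    prev_pred <- pred_set
    records[[k]] <- list(index = cur$index, masks = pred_set,
                         probs = out$probs, prior_source = prior_source,
                         memory = if (store_memory) mem_in)
  }
  structure(list(patient_id = series$patient_id, prior_mode = prior_mode,
                 variant = model$config$variant, fractions = records),
            class = "course_prediction")
}

#' @export
print.course_prediction <- function(x, ...) {
  cat("<course_prediction> patient ", x$patient_id, ", ", x$variant,
      ", mode ", x$prior_mode, ", ", length(x$fractions), " fraction(s)\n",
      sep = "")
  invisible(x)
}
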