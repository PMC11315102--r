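#' Construct an image volume
#'
#' A 3D scalar image on a regular grid with anisotropic voxel spacing. This
#' is the container used for every image role in an adaptive course: the
#' planning CT, the per-fraction CBCT, or the synthetic CT derived from it.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, voxel size in mm along each axis.
#' @return An object of class `image_volume` with fields `data` and
#'   `spacing`.
#' @examples
#' img <- image_volume(array(0, c(8, 8, 8)))
#' dim(img$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 8L))
    stop("all image dimensions must be >= 8", call. = FALSE)
  if (!all(is.finite(data)))
    stop("image intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing), collapse = "x"),
      " mm, intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' Construct a structure set
#'
#' An ordered, named collection of binary masks sharing one grid — the
#' contours of one fraction (targets and organs-at-risk).
#'
#' @param masks named list of 3D binary arrays (values 0/1), all the same
#'   shape. Structure order is the list order.
#' @return An object of class `structure_set`.
#' @examples
#' m <- array(0, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1
#' ss <- structure_set(list(organ = m))
#' names(ss$masks)
#' @export
structure_set <- function(masks) {
  if (!is.list(masks))
    stop("masks must be a named list of binary arrays", call. = FALSE)
  nm <- names(masks)
  if (length(masks) > 0L && (is.null(nm) || anyDuplicated(nm) || any(nm == "")))
    stop("structure names must be unique and non-empty", call. = FALSE)
  shp <- NULL
  masks <- lapply(masks, function(m) {
    m <- as.array(m)
    if (length(dim(m)) != 3L)
      stop("each mask must be a 3D array", call. = FALSE)
    if (!all(m %in% c(0, 1)))
      stop("mask values must be 0 or 1", call. = FALSE)
    m
  })
  if (length(masks) > 0L) {
    shp <- dim(masks[[1L]])
    for (m in masks)
      if (!identical(dim(m), shp))
        stop("all masks must share one shape", call. = FALSE)
  }
  structure(list(masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", length(x$masks), " structure(s)\n", sep = "")
  for (nm in names(x$masks))
    cat("  ", nm, ": ", sum(x$masks[[nm]]), " voxels\n", sep = "")
  invisible(x)
}

#' Construct a displacement field
#'
#' A dense per-voxel displacement (a DVF) on the same grid as its target
#' image. Displacements are in voxel units, component order (d, h, w), and
#' are applied with the pull (backward-warp) convention: the warped image at
#' voxel v samples the source at v + field(v).
#'
#' @param vectors 4D numeric array, dim `c(D, H, W, 3)`.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors) {
  vectors <- as.array(vectors)
  dm <- dim(vectors)
  if (length(dm) != 4L || dm[4L] != 3L)
    stop("displacement field must have dim c(D, H, W, 3)", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("displacements must be finite", call. = FALSE)
  structure(list(vectors = vectors), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  nrm <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat("<displacement_field> ", paste(dim(x$vectors)[1:3], collapse = "x"),
      " grid, max |v| = ", format(max(nrm)), " voxels\n", sep = "")
  invisible(x)
}

#' Construct a fraction record
#'
#' One treatment fraction: its image and ground-truth contours, plus a
#' chronological index and a provenance tag.
#'
#' @param index integer fraction number, starting at 1.
#' @param image an [image_volume()].
#' @param contours a [structure_set()] on the same grid.
#' @param provenance `"simulated"` or `"clinical-like"`.
#' @return An object of class `fraction_record`.
#' @export
fraction_record <- function(index, image, contours,
                            provenance = c("simulated", "clinical-like")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(image, "image_volume"), inherits(contours, "structure_set"))
  index <- as.integer(index)
  if (index < 1L) stop("fraction index must be >= 1", call. = FALSE)
  if (length(contours$masks) > 0L &&
      !identical(dim(image$data), dim(contours$masks[[1L]])))
    stop("fraction image and contours must share one grid", call. = FALSE)
  structure(list(index = index, image = image, contours = contours,
                 provenance = provenance), class = "fraction_record")
}

#' Construct a patient series
#'
#' The unit over which LSTM memory lives: a planning image with contours
#' followed by the ordered fractions of one treatment course.
#'
#' @param patient_id character identifier.
#' @param planning_image an [image_volume()] (planning-CT role).
#' @param planning_contours a [structure_set()] on the planning grid.
#' @param fractions list of [fraction_record()]s with indices 1, 2, ...
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, planning_image, planning_contours,
                           fractions) {
  stopifnot(inherits(planning_image, "image_volume"),
            inherits(planning_contours, "structure_set"))
  if (length(fractions) < 1L)
    stop("a patient series needs at least one fraction", call. = FALSE)
  idx <- vapply(fractions, function(f) f$index, integer(1))
  if (!identical(idx, seq_along(fractions)))
    stop("fraction indices must be 1, 2, ... in order", call. = FALSE)
  shp <- dim(planning_image$data)
  for (f in fractions)
    if (!identical(dim(f$image$data), shp))
      stop("all fraction grids must match the planning grid", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 planning_image = planning_image,
                 planning_contours = planning_contours,
                 fractions = fractions), class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat("<patient_series> ", x$patient_id, ": ",
      paste(dim(x$planning_image$data), collapse = "x"), " grid, ",
      length(x$planning_contours$masks), " structure(s), ",
      length(x$fractions), " fraction(s)\n", sep = "")
  invisible(x)
}
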