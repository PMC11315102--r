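# NIfTI-1 persistence for the package's containers (via RNifti). Images and
# masks are .nii.gz with spacing in the header; displacement fields are 4D
# with the last axis holding the (d, h, w) vector components.

#' Write and read an image volume as NIfTI
#'
#' @param img an [image_volume()].
#' @param path output `.nii.gz` path.
#' @return `write_image_volume()` returns `path` invisibly;
#'   `read_image_volume()` returns an [image_volume()].
#' @export
write_image_volume <- function(img, path) {
  stopifnot(inherits(img, "image_volume"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_image_volume
#' @export
read_image_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  image_volume(array(as.numeric(nii), dim = dim(nii)),
               spacing = RNifti::pixdim(nii)[1:3])
}

#' Write and read a structure set as per-structure NIfTI masks
#'
#' Each structure is one binary `.nii.gz` named `<structure>.nii.gz` under
#' `dir`; a `structures.json` manifest records order.
#'
#' @param ss a [structure_set()].
#' @param dir output directory (created if needed).
#' @param spacing voxel spacing written into each mask header.
#' @return `write_structure_set()` returns `dir` invisibly;
#'   `read_structure_set()` returns a [structure_set()].
#' @export
write_structure_set <- function(ss, dir, spacing = c(1, 1, 1)) {
  stopifnot(inherits(ss, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(ss$masks)) {
    nii <- RNifti::asNifti(ss$masks[[nm]])
    RNifti::pixdim(nii) <- spacing
    RNifti::writeNifti(nii, file.path(dir, paste0(nm, ".nii.gz")))
  }
  jsonlite::write_json(list(structures = names(ss$masks)),
                       file.path(dir, "structures.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "structures.json"),
                             simplifyVector = TRUE)
  masks <- lapply(man$structures, function(nm) {
    nii <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    array(round(as.numeric(nii)), dim = dim(nii))
  })
  names(masks) <- man$structures
  structure_set(masks)
}

#' Write and read a displacement field as 4D NIfTI
#'
#' @param dvf a [displacement_field()].
#' @param path output `.nii.gz` path.
#' @return `write_displacement_field()` returns `path` invisibly;
#'   `read_displacement_field()` returns a [displacement_field()].
#' @export
write_displacement_field <- function(dvf, path) {
  stopifnot(inherits(dvf, "displacement_field"))
  RNifti::writeNifti(RNifti::asNifti(dvf$vectors), path)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  nii <- RNifti::readNifti(path)
  displacement_field(array(as.numeric(nii), dim = dim(nii)))
}

#' Write and read a patient series on disk
#'
#' Layout: `patient_<id>/planning/{image.nii.gz, structures...}` and
#' `patient_<id>/fx_<k>/{image.nii.gz, structures...}`, plus a JSON manifest
#' with fraction order and provenance.
#'
#' @param series a [patient_series()].
#' @param root directory under which `patient_<id>` is created.
#' @return `write_patient_series()` returns the series directory invisibly;
#'   `read_patient_series()` returns a [patient_series()].
#' @export
write_patient_series <- function(series, root) {
  stopifnot(inherits(series, "patient_series"))
  pdir <- file.path(root, paste0("patient_", series$patient_id))
  sp <- series$planning_image$spacing
  dir.create(file.path(pdir, "planning"), recursive = TRUE,
             showWarnings = FALSE)
  write_image_volume(series$planning_image,
                     file.path(pdir, "planning", "image.nii.gz"))
  write_structure_set(series$planning_contours, file.path(pdir, "planning"),
                      spacing = sp)
  for (f in series$fractions) {
    fdir <- file.path(pdir, sprintf("fx_%d", f$index))
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    write_image_volume(f$image, file.path(fdir, "image.nii.gz"))
    write_structure_set(f$contours, fdir, spacing = sp)
  }
  jsonlite::write_json(
    list(patient_id = series$patient_id,
         fractions = lapply(series$fractions, function(f)
           list(index = f$index, provenance = f$provenance))),
    file.path(pdir, "manifest.json"), auto_unbox = TRUE)
  invisible(pdir)
}

#' @rdname write_patient_series
#' @param path the `patient_<id>` directory written by
#'   `write_patient_series()`.
#' @export
read_patient_series <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = FALSE)
  planning_image <- read_image_volume(file.path(path, "planning",
                                                "image.nii.gz"))
  planning_contours <- read_structure_set(file.path(path, "planning"))
  fractions <- lapply(man$fractions, function(fm) {
    fdir <- file.path(path, sprintf("fx_%d", fm$index))
    fraction_record(fm$index, read_image_volume(file.path(fdir,
                                                          "image.nii.gz")),
                    read_structure_set(fdir), provenance = fm$provenance)
  })
  patient_series(man$patient_id, planning_image, planning_contours, fractions)
}
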