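# Segmentation evaluation: Dice overlap, Hausdorff surface distances,
# course-level metric tables and the pooled paired t-test.

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` on binary masks. Two empty masks agree perfectly
#' (1.0); exactly one empty mask scores 0.0.
#'
#' @param a,b binary 3D arrays of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1.0)
  if (sa == 0 || sb == 0) return(0.0)
  2 * sum(a * b) / (sa + sb)
}

#' Hausdorff distance between two masks
#'
#' Symmetric surface distances between the boundary voxels of two binary
#' masks (a boundary voxel is foreground with a 6-neighbour background or
#' on the volume edge), in mm via the voxel spacing. `hd` is the maximum
#' over both directed distances; `hd95` the maximum of the two directed
#' 95th percentiles.
#'
#' @param a,b nonempty binary 3D arrays of the same shape.
#' @param spacing voxel size in mm, length 3.
#' @return `list(hd = , hd95 = )` in mm.
#' @export
hausdorff_distance <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  if (sum(a) == 0 || sum(b) == 0)
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  dm <- dim(a)
  ds <- cpp_surface_dists(a, b, dm[1], dm[2], dm[3], as.numeric(spacing))
  list(hd = max(max(ds$ab), max(ds$ba)),
       hd95 = max(quantile(ds$ab, 0.95, names = FALSE),
                  quantile(ds$ba, 0.95, names = FALSE)))
}

#' Paired t-test on pooled metric arrays
#'
#' Two-sided paired t-test with n-1 degrees of freedom, as applied to the
#' concatenated per-structure score arrays of two models. Pooling across
#' structures mixes non-independent observations; a per-structure test is
#' available via [summarize_metrics()]'s atoms and this same function.
#'
#' @param a,b equal-length numeric vectors of paired scores (n >= 2).
#' @return `list(t = , p = , df = )`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired samples must have equal length >= 2", call. = FALSE)
  d <- a - b
  if (sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined",
         call. = FALSE)
  res <- t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Evaluate a predicted course against ground truth
#'
#' One row per (fraction, structure): Dice, Hausdorff and HD95 (the
#' distances are `NA` when either mask is empty).
#'
#' @param prediction a `course_prediction` from [run_course()], or a list
#'   of predicted [structure_set()]s (one per fraction).
#' @param truth the [patient_series()] holding ground-truth contours.
#' @param model_label label stored in the `model` column.
#' @return data.frame with columns patient, fraction, structure, dsc,
#'   hd_mm, hd95_mm, model.
#' @export
evaluate_course <- function(prediction, truth,
                            model_label = NULL) {
  stopifnot(inherits(truth, "patient_series"))
  if (inherits(prediction, "course_prediction")) {
    sets <- lapply(prediction$fractions, function(f) f$masks)
    if (is.null(model_label)) model_label <- prediction$variant
  } else {
    sets <- prediction
    if (is.null(model_label)) model_label <- "model"
  }
  spacing <- truth$planning_image$spacing
  rows <- list()
  for (k in seq_along(sets)) {
    gt <- truth$fractions[[k]]$contours
    for (nm in names(gt$masks)) {
      pm <- sets[[k]]$masks[[nm]]
      gm <- gt$masks[[nm]]
      if (sum(pm) > 0 && sum(gm) > 0) {
        hd <- hausdorff_distance(pm, gm, spacing)
      } else {
        hd <- list(hd = NA_real_, hd95 = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient = truth$patient_id, fraction = k, structure = nm,
        dsc = dice_coefficient(pm, gm), hd_mm = hd$hd, hd95_mm = hd$hd95,
        model = model_label)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate metric atoms
#'
#' Per-structure mean and sd across all (patient, fraction) pairs, the
#' per-fraction mean across patients (the fraction–Dice curve), and the
#' flat mean over the pooled structure array.
#'
#' @param atoms data.frame as returned by [evaluate_course()] (rows from
#'   several patients may be concatenated).
#' @return `list(per_structure = , per_fraction = , overall = )`.
#' @export
summarize_metrics <- function(atoms) {
  stopifnot(nrow(atoms) > 0L)
  per_structure <- do.call(rbind, lapply(split(atoms, atoms$structure),
    function(g) data.frame(structure = g$structure[1],
                           mean_dsc = mean(g$dsc),
                           sd_dsc = if (nrow(g) > 1) sd(g$dsc) else 0,
                           n = nrow(g))))
  rownames(per_structure) <- NULL
  per_fraction <- aggregate(dsc ~ fraction, data = atoms, FUN = mean)
  names(per_fraction)[2] <- "mean_dsc"
  list(per_structure = per_structure, per_fraction = per_fraction,
       overall = mean(atoms$dsc))
}

#' Plot fraction–Dice curves
#'
#' Mean Dice per fraction for one or more models on one axis system.
#'
#' @param atoms data.frame of metric atoms with a `model` column.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the fraction-by-model matrix of mean Dice.
#' @export
plot_fraction_dice <- function(atoms, ...) {
  tab <- tapply(atoms$dsc, list(atoms$fraction, atoms$model), mean)
  graphics::matplot(as.integer(rownames(tab)), tab, type = "b", pch = 16,
                    lty = 1, xlab = "fraction", ylab = "mean DSC",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = colnames(tab),
                   col = seq_len(ncol(tab)), lty = 1, pch = 16, bty = "n")
  invisible(tab)
}
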