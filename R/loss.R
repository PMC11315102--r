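# Segmentation losses on plain arrays (the differentiable versions used in
# training live in nn-ops.R and share the same formulas).

#' Soft Dice loss
#'
#' `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, averaged over
#' structure channels. Probabilities in, binary targets in.
#'
#' @param pred probability array; either `c(D,H,W)` or `c(D,H,W,C)`.
#' @param target binary array of the same shape.
#' @param eps smoothing constant (default `1e-6`).
#' @return Scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ", call. = FALSE)
  if (length(dim(pred)) == 3L) {
    dim(pred) <- c(dim(pred), 1L)
    dim(target) <- dim(pred)
  }
  C <- dim(pred)[4L]
  pm <- matrix(pred, ncol = C)
  tm <- matrix(target, ncol = C)
  dice_c <- (2 * colSums(pm * tm) + eps) / (colSums(pm) + colSums(tm) + eps)
  mean(1 - dice_c)
}

#' Binary cross-entropy loss
#'
#' Voxelwise mean of `-(g*log(p) + (1-g)*log(1-p))` with probabilities
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @inheritParams soft_dice_loss
#' @param clamp clamping bound for probabilities.
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, target, clamp = 1e-7) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ", call. = FALSE)
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Composite training loss
#'
#' Equally weighted sum of binary cross-entropy and soft Dice:
#' `0.5 * BCE + 0.5 * Dice`.
#'
#' @inheritParams soft_dice_loss
#' @return Scalar loss.
#' @export
composite_loss <- function(pred, target) {
  0.5 * bce_loss(pred, target) + 0.5 * soft_dice_loss(pred, target)
}
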