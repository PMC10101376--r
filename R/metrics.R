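# Segmentation / detection performance metrics used as GA fitness terms.

#' Overlap and confusion-matrix metrics between two masks
#'
#' @param pred,ref logical arrays of identical shape (prediction and
#'   reference).
#' @return the metric value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, ref) {
  i <- sum(pred & ref)
  den <- sum(pred) + sum(ref)
  if (den == 0) return(1)
  2 * i / den
}

#' @rdname dice_coefficient
#' @export
sensitivity_metric <- function(pred, ref) {
  if (sum(ref) == 0) return(1)
  sum(pred & ref) / sum(ref)
}

#' @rdname dice_coefficient
#' @export
specificity_metric <- function(pred, ref) {
  tn <- sum(!pred & !ref)
  den <- sum(!ref)
  if (den == 0) return(1)
  tn / den
}

#' @rdname dice_coefficient
#' @export
precision_metric <- function(pred, ref) {
  if (sum(pred) == 0) return(0)
  sum(pred & ref) / sum(pred)
}

#' Landmark-distance fitness
#'
#' Squared-error point metric mapped into `[0, 1]`:
#' `1 / (1 + (d / scale)^2)` where `d` is the Euclidean distance in mm
#' (so `scale` mm of error halves the fitness).
#'
#' @param pred,ref point coordinates in mm.
#' @param scale softening scale in mm (default 10).
#' @return fitness in `[0, 1]`.
#' @export
landmark_fitness <- function(pred, ref, scale = 10) {
  d2 <- sum((as.numeric(pred) - as.numeric(ref))^2)
  1 / (1 + d2 / scale^2)
}
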