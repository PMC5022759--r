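#' Root-mean-square error between two maps
#'
#' `sqrt(mean((P - G)^2))` over all pixels. On 0/1 binary maps this reduces to
#' the square root of the mismatch fraction, so it is invariant to image size
#' for a fixed mismatch rate.
#'
#' @param pred,ref Numeric, integer or logical matrices of the same shape and
#'   label convention.
#' @return Non-negative scalar; 0 iff the maps are identical.
#' @export
rms_error <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    data_error("prediction and reference shapes differ")
  sqrt(mean((as.numeric(pred) - as.numeric(ref))^2))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    data_error("mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Evaluate a segmentation against a reference
#'
#' Computes the RMS error of each class's binary map, their mean (the
#' headline `rms`), the RMS over the integer label maps, the Dice coefficient
#' per class and the pixel counts.
#'
#' @param pred Integer label matrix (0 = background, 1 = CSF, 2 = GM,
#'   3 = WM).
#' @param ref A `reference_segmentation` (see [as_reference()]).
#' @return An `eval_report` list: `rms`, `per_class_rms`, `label_rms`,
#'   `dice_per_class`, `pixel_counts`.
#' @export
evaluate_segmentation <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref$labels)))
    data_error("prediction and reference shapes differ")
  per_class_rms <- vapply(names(tissue_classes), function(cls)
    rms_error(pred == tissue_classes[[cls]], ref[[cls]]), numeric(1))
  dice_per_class <- vapply(names(tissue_classes), function(cls)
    dice_coefficient(pred == tissue_classes[[cls]], ref[[cls]]), numeric(1))
  counts <- vapply(names(tissue_classes), function(cls)
    c(pred = sum(pred == tissue_classes[[cls]]), ref = sum(ref[[cls]])),
    numeric(2))
  structure(list(rms = mean(per_class_rms),
                 per_class_rms = per_class_rms,
                 label_rms = rms_error(pred, ref$labels),
                 dice_per_class = dice_per_class,
                 pixel_counts = counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("segmentation evaluation: rms=%.4f (label rms=%.4f)\n",
              x$rms, x$label_rms))
  for (cls in names(x$per_class_rms))
    cat(sprintf("  %-3s rms=%.4f dice=%.4f\n", cls,
                x$per_class_rms[[cls]], x$dice_per_class[[cls]]))
  invisible(x)
}
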