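# Pixelwise confusion-matrix metrics and overlap coefficients.

#' Pixelwise confusion counts
#'
#' Tallies TP/TN/FP/FN between a binary predicted mask and the binary
#' ground truth, lesion = positive. Thresholding soft predictions is the
#' caller's explicit step (conventionally at 0.5); non-binary input is an
#' error rather than silently thresholded.
#'
#' @param pred_mask,gt_mask Binary (0/1 or logical) matrices of equal shape.
#' @return Object of class \code{confusion_counts}: list TP, TN, FP, FN.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1)))
    stop("inputs must be binary (threshold soft predictions first, e.g. at 0.5)")
  p <- pred_mask > 0; g <- gt_mask > 0
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Acc = (TP+TN)/total, Pre = TP/(TP+FP), Re = TP/(TP+FN), F1 the harmonic
#' mean of Pre and Re, IOU = TP/(TP+FP+FN), DSC = 2TP/(2TP+FP+FN). Ratios
#' with empty denominators are reported as NA, never silently as 0 or 1.
#' The identity DSC = 2*IOU/(1+IOU) holds whenever both are defined.
#'
#' @param counts A \code{\link{confusion_counts}}.
#' @return Object of class \code{metric_report}: list Acc, Pre, Re, F1,
#'   IOU, DSC.
#' @export
seg_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  Acc <- rat(TP + TN, total)
  Pre <- rat(TP, TP + FP)
  Re <- rat(TP, TP + FN)
  F1 <- if (!is.na(Pre) && !is.na(Re) && (Pre + Re) > 0)
    2 * Pre * Re / (Pre + Re) else NA_real_
  IOU <- rat(TP, TP + FP + FN)
  DSC <- rat(2 * TP, 2 * TP + FP + FN)
  structure(list(Acc = Acc, Pre = Pre, Re = Re, F1 = F1, IOU = IOU, DSC = DSC),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Acc %.4f  Pre %.4f  Re %.4f  F1 %.4f  IOU %.4f  DSC %.4f\n",
              x$Acc, x$Pre, x$Re, x$F1, x$IOU, x$DSC))
  invisible(x)
}

#' Overlap coefficients of two masks
#'
#' Set-wise intersection-over-union and Dice coefficient of the predicted
#' and ground-truth lesion pixel sets.
#'
#' @param pred,gt Binary matrices of equal shape.
#' @return List with \code{IOU} and \code{DSC} (NA when both masks are
#'   empty).
#' @export
overlap_coefficients <- function(pred, gt) {
  m <- seg_metrics(confusion_counts(pred, gt))
  list(IOU = m$IOU, DSC = m$DSC)
}
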