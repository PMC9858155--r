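# Training objectives: focal classification loss, distance-IoU box loss,
# binary cross-entropy mask / edge / region losses, and their combination
# into the segmentation and total losses.

.EPS_PROB <- 1e-7

.clamp_prob <- function(p) clamp(p, .EPS_PROB, 1 - .EPS_PROB)

#' Loss configuration
#'
#' @param alpha Focal weighting factor in (0, 1] (default 0.25).
#' @param gamma Focal focusing exponent >= 0 (default 2).
#' @param p Control exponent of the center-distance penalty in the box loss
#'   (default 2, the distance-IoU form).
#' @return Object of class \code{loss_config}.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2.0, p = 2.0) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (p <= 0) stop("p must be > 0")
  structure(list(alpha = alpha, gamma = gamma, p = p), class = "loss_config")
}

#' Focal classification loss
#'
#' Mean over samples of \eqn{-\alpha (1 - \rho)^\gamma \log \rho}, where
#' \eqn{\rho} is the predicted probability of the true class. With
#' \eqn{\alpha = 1, \gamma = 0} this reduces to cross-entropy. Probabilities
#' are clamped at 1e-7 to keep the loss finite.
#'
#' @param rho Numeric vector of true-class probabilities in (0, 1].
#' @param config A \code{\link{loss_config}}.
#' @return Non-negative scalar.
#' @export
focal_cls_loss <- function(rho, config = loss_config()) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  rho <- .clamp_prob(rho)
  mean(-config$alpha * (1 - rho)^config$gamma * log(rho))
}

.box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

#' Distance-IoU style bounding-box loss
#'
#' \eqn{l_{box} = (1 - IoU) + (d / c)^p} with d the distance between box
#' centers and c the diagonal of the smallest box enclosing both. Zero
#' exactly for identical boxes, and invariant under joint translation.
#'
#' @param pred,gt Numeric length-4 boxes \code{c(x1, y1, x2, y2)},
#'   \code{x1 < x2}, \code{y1 < y2}.
#' @param config A \code{\link{loss_config}} (exponent \code{p}).
#' @return Non-negative scalar.
#' @export
box_loss <- function(pred, gt, config = loss_config()) {
  if (!(gt[1] < gt[3] && gt[2] < gt[4])) stop("degenerate ground-truth box")
  if (!(pred[1] < pred[3] && pred[2] < pred[4])) stop("degenerate predicted box")
  iou <- .box_iou(pred, gt)
  cp <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2)
  cg <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2)
  d <- sqrt(sum((cp - cg)^2))
  cw <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  ch <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  cc <- sqrt(cw^2 + ch^2)
  as.numeric((1 - iou) + (d / cc)^config$p)
}

.bce_mean <- function(probs, target) {
  probs <- .clamp_prob(as.numeric(probs))
  target <- as.numeric(target)
  if (length(probs) != length(target)) stop("shape mismatch")
  mean(-(target * log(probs) + (1 - target) * log(1 - probs)))
}

#' Average binary cross-entropy mask loss
#'
#' Per-pixel BCE of the sigmoid mask-head probabilities against the binary
#' ground truth, averaged over the mask head's pixels. Computed for the
#' matched foreground class only, decoupling mask quality from the
#' classification task.
#'
#' @param pred_mask_probs Probability array/matrix in (0, 1).
#' @param gt_mask Binary array/matrix of identical shape.
#' @return Non-negative scalar.
#' @export
mask_loss <- function(pred_mask_probs, gt_mask) {
  if (!all(dim(as.array(pred_mask_probs)) == dim(as.array(gt_mask))))
    stop("shape mismatch between prediction and ground truth")
  .bce_mean(pred_mask_probs, gt_mask)
}

#' Edge supervision loss
#'
#' Binary cross-entropy between the BPP edge-candidate map and the
#' rasterized boundary key points, averaged over pixels.
#'
#' @param D_pred Edge probability map in (0, 1).
#' @param D_GT Binary key-point target of identical shape.
#' @return Non-negative scalar.
#' @export
edge_loss <- function(D_pred, D_GT) {
  if (!all(dim(as.array(D_pred)) == dim(as.array(D_GT))))
    stop("shape mismatch between D_pred and D_GT")
  .bce_mean(D_pred, D_GT)
}

#' Region supervision loss
#'
#' Same contract as \code{\link{edge_loss}}, applied to the region map
#' predicted under edge-attention guidance versus the ground-truth region.
#'
#' @param Reg_pred Region probability map in (0, 1).
#' @param Reg_GT Binary ground-truth region of identical shape.
#' @return Non-negative scalar.
#' @export
region_loss <- function(Reg_pred, Reg_GT) {
  if (!all(dim(as.array(Reg_pred)) == dim(as.array(Reg_GT))))
    stop("shape mismatch between Reg_pred and Reg_GT")
  .bce_mean(Reg_pred, Reg_GT)
}

#' Combine loss components into the training bundle
#'
#' \code{l_seg = l_cls + l_box + l_mask} and
#' \code{l_total = l_seg + l_edge + l_reg}. The supervision ablation flags
#' zero the edge (ES off) and/or region (RS off) terms.
#'
#' @param l_cls,l_box,l_mask,l_edge,l_reg Finite non-negative scalars.
#' @param use_es,use_rs Logical supervision flags (default TRUE).
#' @return Object of class \code{loss_bundle} with fields l_cls, l_box,
#'   l_mask, l_edge, l_reg, l_seg, l_total.
#' @export
total_loss <- function(l_cls = 0, l_box = 0, l_mask = 0, l_edge = 0, l_reg = 0,
                       use_es = TRUE, use_rs = TRUE) {
  comp <- c(l_cls = l_cls, l_box = l_box, l_mask = l_mask,
            l_edge = l_edge, l_reg = l_reg)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad))
    stop(sprintf("non-finite loss component(s): %s", paste(bad, collapse = ", ")))
  if (!use_es) l_edge <- 0
  if (!use_rs) l_reg <- 0
  l_seg <- l_cls + l_box + l_mask
  structure(list(l_cls = l_cls, l_box = l_box, l_mask = l_mask,
                 l_edge = l_edge, l_reg = l_reg,
                 l_seg = l_seg, l_total = l_seg + l_edge + l_reg),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f (cls %.4f + box %.4f + mask %.4f | edge %.4f + region %.4f)\n",
    x$l_total, x$l_cls, x$l_box, x$l_mask, x$l_edge, x$l_reg))
  invisible(x)
}
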