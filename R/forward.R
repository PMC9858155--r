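# Training step (forward + losses + hand-chained backward) and inference.

# Anchor labeling: 1 = positive (IoU >= 0.5 or best anchor), 0 = negative
# (IoU < 0.3), NA = ignored.
.rpn_targets <- function(anchors, gt_box) {
  iou <- .iou_many(anchors[, 1:4, drop = FALSE], gt_box)
  lab <- rep(NA_real_, nrow(anchors))
  lab[iou < 0.3] <- 0
  lab[iou >= 0.5] <- 1
  lab[which.max(iou)] <- 1
  lab
}

# Random negative RoI that barely overlaps the lesion (for the class head).
.sample_negative_roi <- function(n, gt_box, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    w <- stats::runif(1, n / 6, n / 2); h <- stats::runif(1, n / 6, n / 2)
    x1 <- stats::runif(1, -0.5, n - 0.5 - w); y1 <- stats::runif(1, -0.5, n - 0.5 - h)
    b <- c(x1, y1, x1 + w, y1 + h)
    if (.iou_many(matrix(b, 1), gt_box) < 0.1) return(b)
  }
  NULL
}

.jitter_box <- function(box, n, frac = 0.1) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  b <- box + c(stats::runif(1, -frac, frac) * w, stats::runif(1, -frac, frac) * h,
               stats::runif(1, -frac, frac) * w, stats::runif(1, -frac, frac) * h)
  if (b[1] >= b[3] - 2 || b[2] >= b[4] - 2) b <- box
  .clamp_box(b, n)
}

# Map full-image key points into head-grid coordinates and rasterize.
.keypoints_to_head <- function(points, box, head_size, radius = 1) {
  if (is.null(points) || nrow(points) == 0)
    return(matrix(0L, head_size, head_size))
  u <- (points[, 1] - box[1]) / (box[3] - box[1]) * head_size - 0.5
  v <- (points[, 2] - box[2]) / (box[4] - box[2]) * head_size - 0.5
  keep <- u > -0.5 & u < head_size - 0.5 & v > -0.5 & v < head_size - 0.5
  if (!any(keep)) return(matrix(0L, head_size, head_size))
  rasterize_keypoints(cbind(clamp(u[keep], 0, head_size - 1),
                            clamp(v[keep], 0, head_size - 1)),
                      c(head_size, head_size), radius = radius)
}

# One optimization-ready step on a single image: forward, all loss
# components, and gradient accumulation. loss_weights lets tests isolate a
# single objective's gradient flow.
.train_step <- function(net, image, mask, keypoints = NULL,
                        lcfg = loss_config(),
                        loss_weights = c(cls = 1, box = 1, mask = 1,
                                         edge = 1, reg = 1),
                        n_neg = 2L, backward = TRUE) {
  cfg <- net$config
  n <- cfg$input_size
  fl <- cfg$flags
  stopifnot(nrow(image) == n, ncol(image) == n)
  x <- array(image, dim = c(n, n, 1L))
  tr <- .trunk_forward(net, x, train = TRUE)
  gt_box <- .clamp_box(mask_bbox(mask), n)

  # --- RPN losses ----------------------------------------------------------
  anch <- net$anchors
  lab <- .rpn_targets(anch, gt_box)
  A <- length(cfg$anchor_ratios)
  cls_flat <- lapply(tr$rpn, function(r) as.vector(r$cls))
  probs <- lapply(cls_flat, function(z) 1 / (1 + exp(-z)))
  npos <- sum(lab == 1, na.rm = TRUE)
  l_rpn_cls <- 0
  dcls <- lapply(tr$rpn, function(r) array(0, dim = dim(r$cls)))
  dbox <- lapply(tr$rpn, function(r) array(0, dim = dim(r$box)))
  for (li in 1:5) {
    sel <- anch[, "level"] == li
    labi <- lab[sel]
    use <- !is.na(labi)
    if (!any(use)) next
    p <- probs[[li]][anch[sel, "idx"][use]]
    rho <- ifelse(labi[use] == 1, p, 1 - p)
    rhoc <- clamp(rho, .EPS_PROB, 1 - .EPS_PROB)
    l_rpn_cls <- l_rpn_cls +
      sum(-lcfg$alpha * (1 - rhoc)^lcfg$gamma * log(rhoc))
    drho <- .dfocal_drho(rho, lcfg$alpha, lcfg$gamma)
    dz <- drho * p * (1 - p) * ifelse(labi[use] == 1, 1, -1)
    tmp <- numeric(length(probs[[li]]))
    tmp[anch[sel, "idx"][use]] <- dz
    dcls[[li]] <- dcls[[li]] + array(tmp, dim = dim(tr$rpn[[li]]$cls))
  }
  norm_cls <- max(1, npos)
  l_rpn_cls <- l_rpn_cls / norm_cls
  for (li in 1:5) dcls[[li]] <- dcls[[li]] / norm_cls * loss_weights["cls"]

  # RPN box regression on (up to 8) positive anchors
  pos_rows <- which(lab == 1)
  if (length(pos_rows) > 8) pos_rows <- pos_rows[order(
    -.iou_many(anch[pos_rows, 1:4, drop = FALSE], gt_box))][1:8]
  l_rpn_box <- 0
  for (pr in pos_rows) {
    li <- anch[pr, "level"]
    HlWl <- dim(tr$rpn[[li]]$box)[1] * dim(tr$rpn[[li]]$box)[2]
    ai <- (anch[pr, "idx"] - 1) %/% HlWl       # ratio slot
    cell <- (anch[pr, "idx"] - 1) %% HlWl
    t_off <- HlWl * (4 * ai) + cell + 1
    tvec <- as.vector(tr$rpn[[li]]$box)[t_off + HlWl * (0:3)]
    bb <- .decode_box(anch[pr, 1:4], tvec)
    if (bb[1] < bb[3] && bb[2] < bb[4]) {
      l_rpn_box <- l_rpn_box + box_loss(bb, gt_box, lcfg)
      g <- .dbox_ddeltas(anch[pr, 1:4], tvec, gt_box, lcfg)
      tmp <- as.vector(dbox[[li]])
      tmp[t_off + HlWl * (0:3)] <- tmp[t_off + HlWl * (0:3)] +
        g / length(pos_rows) * loss_weights["box"]
      dbox[[li]] <- array(tmp, dim = dim(dbox[[li]]))
    }
  }
  l_rpn_box <- l_rpn_box / max(1, length(pos_rows))

  # --- RoI heads (P2 features) --------------------------------------------
  # The positive RoI alternates between a jittered ground-truth box and the
  # network's current top proposal (when it overlaps the lesion), so the
  # box/mask heads see the same RoI distribution at train and test time.
  P2 <- tr$P[[1]]
  roi <- .jitter_box(gt_box, n)
  if (stats::runif(1) < 0.5) {
    best <- which.max(unlist(lapply(tr$rpn, function(r) as.vector(r$cls))))
    anch_b <- net$anchors[best, ]
    lib <- anch_b["level"]
    HlWl <- dim(tr$rpn[[lib]]$box)[1] * dim(tr$rpn[[lib]]$box)[2]
    aib <- (anch_b["idx"] - 1) %/% HlWl
    cellb <- (anch_b["idx"] - 1) %% HlWl
    t_offb <- HlWl * (4 * aib) + cellb + 1
    tvb <- as.vector(tr$rpn[[lib]]$box)[t_offb + HlWl * (0:3)]
    prop <- .clamp_box(.decode_box(anch_b[1:4], tvb), n)
    if (.iou_many(matrix(prop, 1), gt_box) >= 0.3) roi <- prop
  }
  rois <- list(roi)
  for (k in seq_len(n_neg)) {
    nb <- .sample_negative_roi(n, gt_box)
    if (!is.null(nb)) rois[[length(rois) + 1]] <- nb
  }
  feat7 <- lapply(seq_along(rois), function(i)
    net$roi7[[i]]$fwd(P2, .box_to_feat(rois[[i]], 4), TRUE))
  flat <- do.call(rbind, lapply(feat7, as.vector))
  fc <- net$fc_relu$fwd(net$fc1$fwd(flat, TRUE), TRUE)
  logits <- net$cls_fc$fwd(fc, TRUE)              # rows x 2 (bg, lesion)
  deltas <- net$box_fc$fwd(fc, TRUE)              # rows x 4
  pcls <- exp(logits - apply(logits, 1, max))
  pcls <- pcls / rowSums(pcls)
  truth <- c(2L, rep(1L, length(rois) - 1L))      # col 2 = lesion
  rho_head <- pcls[cbind(seq_along(rois), truth)]
  rhoc <- clamp(rho_head, .EPS_PROB, 1 - .EPS_PROB)
  l_head_cls <- mean(-lcfg$alpha * (1 - rhoc)^lcfg$gamma * log(rhoc))
  drho <- .dfocal_drho(rho_head, lcfg$alpha, lcfg$gamma) / length(rois)
  dlogits <- matrix(0, length(rois), 2)
  for (i in seq_along(rois)) {
    onehot <- c(0, 0); onehot[truth[i]] <- 1
    dlogits[i, ] <- drho[i] * rho_head[i] * (onehot - pcls[i, ])
  }
  # head box refinement on the positive RoI
  t_head <- deltas[1, ]
  refined <- .decode_box(rois[[1]], t_head)
  l_head_box <- 0
  ddeltas <- matrix(0, length(rois), 4)
  if (refined[1] < refined[3] && refined[2] < refined[4]) {
    l_head_box <- box_loss(refined, gt_box, lcfg)
    ddeltas[1, ] <- .dbox_ddeltas(rois[[1]], t_head, gt_box, lcfg)
  }

  # --- Mask / attention branch on the positive RoI -------------------------
  hs <- cfg$head_size
  mb <- .mask_branch_forward(net, P2, .box_to_feat(rois[[1]], 4), train = TRUE)
  gt14 <- (roi_align(matrix(as.numeric(mask), n, n), rois[[1]],
                     c(hs, hs), 4L)[, , 1] > 0.5) * 1
  l_mask <- mask_loss(clamp(mb$mprob[, , 1], .EPS_PROB, 1 - .EPS_PROB), gt14)
  npix <- hs * hs
  d_mlog <- array((mb$mprob[, , 1] - gt14) / npix * loss_weights["mask"],
                  dim = c(hs, hs, 1))
  l_edge <- 0; d_p <- NULL
  if (fl$ES && !is.null(mb$Fp)) {
    dgt <- .keypoints_to_head(keypoints, rois[[1]], hs)
    l_edge <- edge_loss(clamp(mb$Fp[, , 1], .EPS_PROB, 1 - .EPS_PROB), dgt)
    pc <- clamp(mb$Fp[, , 1], .EPS_PROB, 1 - .EPS_PROB)
    d_p <- array((pc - dgt) / (pc * (1 - pc)) / npix * loss_weights["edge"],
                 dim = c(hs, hs, 1))
  }
  l_reg <- 0; d_rlog <- NULL
  if (fl$RS && !is.null(mb$rprob)) {
    l_reg <- region_loss(clamp(mb$rprob[, , 1], .EPS_PROB, 1 - .EPS_PROB), gt14)
    d_rlog <- array((mb$rprob[, , 1] - gt14) / npix * loss_weights["reg"],
                    dim = c(hs, hs, 1))
  }

  bundle <- total_loss(l_cls = l_head_cls + l_rpn_cls,
                       l_box = l_head_box + l_rpn_box,
                       l_mask = l_mask, l_edge = l_edge, l_reg = l_reg,
                       use_es = fl$ES, use_rs = fl$RS)

  if (backward) {
    dP2 <- .mask_branch_backward(net, mb, d_mlog, d_rlog, d_p)
    dfc <- net$cls_fc$bwd(dlogits * loss_weights["cls"]) +
      net$box_fc$bwd(ddeltas * loss_weights["box"])
    dflat <- net$fc1$bwd(net$fc_relu$bwd(dfc))
    for (i in seq_along(rois)) {
      d7 <- array(dflat[i, ], dim = dim(feat7[[i]]))
      dP2 <- dP2 + net$roi7[[i]]$bwd(d7)
    }
    dP <- list(dP2, NULL, NULL, NULL, NULL)
    drpn <- lapply(1:5, function(li) list(cls = dcls[[li]], box = dbox[[li]]))
    .trunk_backward(net, dP, drpn)
  }
  bundle
}

#' Run the network on one image
#'
#' Deterministic in evaluation mode: the top-objectness RPN proposal is
#' decoded, refined by the box head, and the mask branch is evaluated on the
#' refined box. The head-resolution mask and boundary maps are bilinearly
#' upsampled into the box and pasted onto a full-resolution canvas.
#'
#' @param net A \code{\link{build_ean}} network.
#' @param image Square grayscale matrix matching the configured input size
#'   (no silent resizing).
#' @param return_features If TRUE, also return the head-mask features
#'   \code{Of}, attention output \code{Z}, edge map \code{F_points} and the
#'   RoI used — the hooks for composing the attention modules as standalone
#'   ops.
#' @return List of class \code{ean_output}: \code{boxes} (proposal and
#'   refined box), \code{class_probs} (background, lesion), \code{mask} and
#'   \code{boundary_map} (full-resolution probability matrices;
#'   boundary_map is NULL when edge attention is disabled).
#' @export
ean_forward <- function(net, image, return_features = FALSE) {
  cfg <- net$config
  n <- cfg$input_size
  if (!is.matrix(image) || nrow(image) != n || ncol(image) != n)
    stop(sprintf("image must be a %dx%d matrix (configured input size)", n, n))
  x <- array(image, dim = c(n, n, 1L))
  tr <- .trunk_forward(net, x, train = FALSE)
  scores <- unlist(lapply(tr$rpn, function(r) as.vector(r$cls)))
  best <- which.max(scores)
  anch <- net$anchors[best, ]
  li <- anch["level"]
  HlWl <- dim(tr$rpn[[li]]$box)[1] * dim(tr$rpn[[li]]$box)[2]
  ai <- (anch["idx"] - 1) %/% HlWl
  cell <- (anch["idx"] - 1) %% HlWl
  t_off <- HlWl * (4 * ai) + cell + 1
  tvec <- as.vector(tr$rpn[[li]]$box)[t_off + HlWl * (0:3)]
  proposal <- .clamp_box(.decode_box(anch[1:4], tvec), n)
  P2 <- tr$P[[1]]
  f7 <- net$roi7[[1]]$fwd(P2, .box_to_feat(proposal, 4), FALSE)
  fc <- net$fc_relu$fwd(net$fc1$fwd(as.vector(f7), FALSE), FALSE)
  logits <- net$cls_fc$fwd(fc, FALSE)
  deltas <- net$box_fc$fwd(fc, FALSE)
  pcls <- exp(logits - max(logits)); pcls <- pcls / sum(pcls)
  refined <- .clamp_box(.decode_box(proposal, as.vector(deltas)), n)
  mb <- .mask_branch_forward(net, P2, .box_to_feat(refined, 4), train = FALSE)
  mask_full <- .paste_patch(mb$mprob[, , 1], refined, n)
  boundary_full <- if (!is.null(mb$Fp)) .paste_patch(mb$Fp[, , 1], refined, n)
    else NULL
  out <- list(boxes = list(proposal = proposal, refined = refined),
              class_probs = c(background = pcls[1], lesion = pcls[2]),
              mask = mask_full, boundary_map = boundary_full)
  if (return_features)
    out <- c(out, list(Of = mb$Of, Z = mb$Z, F_points = mb$Fp, roi = refined))
  structure(out, class = "ean_output")
}

# Bilinear paste of a head-resolution patch into a box on an n x n canvas.
.paste_patch <- function(patch, box, n) {
  out <- matrix(0, n, n)
  hs <- nrow(patch)
  xs <- max(0, ceiling(box[1])):min(n - 1, floor(box[3]))
  ys <- max(0, ceiling(box[2])):min(n - 1, floor(box[4]))
  if (!length(xs) || !length(ys)) return(out)
  u <- (xs - box[1]) / (box[3] - box[1]) * hs - 0.5
  v <- (ys - box[2]) / (box[4] - box[2]) * hs - 0.5
  gu <- rep(u, each = length(v))
  gv <- rep(v, times = length(u))
  vals <- bilinear_interpolate(array(patch, c(hs, hs, 1)), gu, gv)[, 1]
  out[cbind(rep(ys, times = length(xs)) + 1L,
            rep(xs, each = length(ys)) + 1L)] <- vals
  out
}

#' @export
print.ean_output <- function(x, ...) {
  b <- x$boxes$refined
  cat(sprintf("segmentation output: lesion prob %.3f, box [%.1f, %.1f, %.1f, %.1f], mask >0.5 pixels %d\n",
              x$class_probs["lesion"], b[1], b[2], b[3], b[4],
              sum(x$mask > 0.5)))
  invisible(x)
}
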