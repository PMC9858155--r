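# Full segmentation network: residual backbone -> FPN -> RPN -> RoI Align ->
# box/class heads + mask head -> mixed attention -> BPP -> edge-attention
# fusion, with ablation flags mirroring the component study (RA, CA, SA, EA,
# ES, RS).

#' Network configuration
#'
#' Defaults follow the reference layer contract for 512 x 512 inputs
#' (ResNet-50-style backbone stage widths, 256-channel FPN, 1024-d shared
#' fully connected layer, 7 x 7 RoI pooling, 14 x 14 head maps). The tiny
#' preset keeps the full topology — every module present — while shrinking
#' widths and block counts so a CPU forward + backward step on a 64 x 64
#' image runs in tens of milliseconds.
#'
#' @param input_size Square input side in pixels, divisible by 32.
#' @param backbone_blocks Residual block counts for stages C2-C5.
#' @param backbone_widths Output channels of stages C2-C5.
#' @param stem_width Channels of the stem (C1) convolution.
#' @param fpn_channels Channels of every pyramid level P2-P6.
#' @param fc_dim Width of the shared fully connected head layer.
#' @param roi_size RoI Align output for the box/class head (default 7).
#' @param head_size RoI Align output for the mask head (default 14).
#' @param attention_mode "parallel" (default) or one of the serial ablation
#'   wirings "channel_then_spatial", "spatial_then_channel".
#' @param anchor_ratios Aspect ratios of the RPN anchors per level.
#' @param anchor_size_factor Anchor base size as a multiple of the level
#'   stride.
#' @param bpp A \code{\link{bpp_config}} for the boundary points proposal
#'   head.
#' @param flags Named logical list RA (aligned RoI sampling), CA (channel
#'   attention), SA (spatial attention), EA (edge attention incl. BPP), ES
#'   (edge supervision loss), RS (region supervision loss). EA requires CA
#'   or SA; ES requires EA; RS requires ES.
#' @param seed Seed for weight initialization.
#' @param tiny Logical; TRUE applies the desk-scale preset.
#' @return Object of class \code{ean_config}.
#' @export
ean_config <- function(input_size = 512L,
                        backbone_blocks = c(2L, 3L, 22L, 2L),
                        backbone_widths = c(256L, 512L, 1024L, 2048L),
                        stem_width = 64L,
                        fpn_channels = 256L,
                        fc_dim = 1024L,
                        roi_size = 7L,
                        head_size = 14L,
                        attention_mode = "parallel",
                        anchor_ratios = c(0.5, 1, 2),
                        anchor_size_factor = 4,
                        bpp = bpp_config(),
                        flags = list(RA = TRUE, CA = TRUE, SA = TRUE,
                                     EA = TRUE, ES = TRUE, RS = TRUE),
                        seed = 1L,
                        tiny = FALSE) {
  if (tiny) {
    input_size <- 64L
    backbone_blocks <- c(1L, 1L, 1L, 1L)
    backbone_widths <- c(16L, 24L, 32L, 40L)
    stem_width <- 8L
    fpn_channels <- 24L
    fc_dim <- 64L
    bpp <- bpp_config(dilation_rates = c(1L, 2L), reduce_channels = 8L)
  }
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  fl <- utils::modifyList(list(RA = TRUE, CA = TRUE, SA = TRUE, EA = TRUE,
                        ES = TRUE, RS = TRUE), flags)
  if (fl$EA && !(fl$CA || fl$SA))
    stop("inconsistent flags: EA requires CA or SA upstream (component-study row EA without CA/SA does not exist)")
  if (fl$ES && !fl$EA)
    stop("inconsistent flags: ES (edge supervision) requires EA")
  if (fl$RS && !fl$ES)
    stop("inconsistent flags: RS (region supervision) requires ES")
  structure(list(input_size = as.integer(input_size),
                 backbone_blocks = as.integer(backbone_blocks),
                 backbone_widths = as.integer(backbone_widths),
                 stem_width = as.integer(stem_width),
                 fpn_channels = as.integer(fpn_channels),
                 fc_dim = as.integer(fc_dim),
                 roi_size = as.integer(roi_size),
                 head_size = as.integer(head_size),
                 attention_mode = match.arg(attention_mode,
                   c("parallel", "channel_then_spatial", "spatial_then_channel")),
                 anchor_ratios = anchor_ratios,
                 anchor_size_factor = anchor_size_factor,
                 bpp = bpp,
                 flags = fl,
                 seed = as.integer(seed),
                 tiny = tiny),
            class = "ean_config")
}

#' Analytic feature-map shape table
#'
#' Stage and pyramid shapes implied by a configuration, without building the
#' network (for the default 512 config: C1 256x256, C2 128x128 ... C5 16x16;
#' P2 128x128x256 down to P6 8x8x256).
#'
#' @param config A \code{\link{ean_config}}.
#' @return data.frame with layer, height, width, channels.
#' @export
ean_shapes <- function(config) {
  n <- config$input_size
  data.frame(
    layer = c("C1", "C2", "C3", "C4", "C5", "P2", "P3", "P4", "P5", "P6"),
    height = c(n / 2, n / 4, n / 8, n / 16, n / 32,
               n / 4, n / 8, n / 16, n / 32, n / 64),
    width = c(n / 2, n / 4, n / 8, n / 16, n / 32,
              n / 4, n / 8, n / 16, n / 32, n / 64),
    channels = c(config$stem_width, config$backbone_widths,
                 rep(config$fpn_channels, 5)))
}

# Anchor grid over all pyramid levels: matrix (x1, y1, x2, y2) plus level id
# and within-level flat index matching the RPN conv output layout
# (row fastest, then column, then ratio).
.make_anchors <- function(config) {
  n <- config$input_size
  out <- list()
  for (l in 1:5) {
    stride <- 4 * 2^(l - 1)
    Hl <- n / stride
    base <- config$anchor_size_factor * stride
    per <- list()
    for (r in config$anchor_ratios) {
      w <- base / sqrt(r); h <- base * sqrt(r)
      cy <- (rep(seq_len(Hl), times = Hl) - 0.5) * stride - 0.5
      cx <- (rep(seq_len(Hl), each = Hl) - 0.5) * stride - 0.5
      per[[length(per) + 1]] <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    }
    A <- do.call(rbind, per)
    out[[l]] <- cbind(A, level = l, idx = seq_len(nrow(A)))
  }
  do.call(rbind, out)
}

.iou_many <- function(boxes, gt) {
  ix <- pmax(0, pmin(boxes[, 3], gt[3]) - pmax(boxes[, 1], gt[1]))
  iy <- pmax(0, pmin(boxes[, 4], gt[4]) - pmax(boxes[, 2], gt[2]))
  inter <- ix * iy
  ua <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]) +
    (gt[3] - gt[1]) * (gt[4] - gt[2]) - inter
  inter / ua
}

.decode_box <- function(anchor, t) {
  aw <- anchor[3] - anchor[1]; ah <- anchor[4] - anchor[2]
  ax <- (anchor[1] + anchor[3]) / 2; ay <- (anchor[2] + anchor[4]) / 2
  cx <- ax + clamp(t[1], -2, 2) * aw
  cy <- ay + clamp(t[2], -2, 2) * ah
  w <- aw * exp(clamp(t[3], -3, 3))
  h <- ah * exp(clamp(t[4], -3, 3))
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

.clamp_box <- function(box, n, min_size = 3) {
  box[1] <- clamp(box[1], -0.5, n - 0.5 - min_size)
  box[2] <- clamp(box[2], -0.5, n - 0.5 - min_size)
  box[3] <- clamp(box[3], box[1] + min_size, n - 0.5)
  box[4] <- clamp(box[4], box[2] + min_size, n - 0.5)
  box
}

#' Build the segmentation network
#'
#' Assembles the trainable graph for a configuration: stem + 4 residual
#' stages (C2-C5), lateral/top-down FPN producing P2-P6, per-level RPN
#' heads, RoI-Aligned box/class heads, and the mask branch
#' (RoI Align head_size -> two conv blocks = head mask features -> mixed
#' attention -> BPP -> edge-attention fusion -> mask and region
#' predictors). Ablation flags drop the corresponding modules: disabled
#' attention branches become pass-throughs, EA off removes the BPP head and
#' fusion, RS off removes the region predictor, RA off switches RoI
#' sampling to quantized (rounded) coordinates.
#'
#' @param config A \code{\link{ean_config}}.
#' @return Object of class \code{ean_net} (an environment of layers and
#'   parameters). Use \code{\link{ean_forward}} or \code{\link{ean_train}}.
#' @export
build_ean <- function(config) {
  stopifnot(inherits(config, "ean_config"))
  fl <- config$flags
  net <- new.env()
  net$config <- config
  with_local_seed(config$seed, {
    Fc <- config$fpn_channels
    net$stem <- nn_seq(nn_conv2d(1L, config$stem_width, k = 3L, stride = 2L),
                       nn_bn(config$stem_width), nn_relu())
    net$stages <- vector("list", 4)
    cin <- config$stem_width
    for (i in 1:4) {
      w <- config$backbone_widths[i]
      blocks <- list(nn_resblock(cin, w, stride = 2L))
      for (b in seq_len(config$backbone_blocks[i] - 1L))
        blocks[[length(blocks) + 1]] <- nn_resblock(w, w)
      net$stages[[i]] <- do.call(nn_seq, blocks)
      cin <- w
    }
    net$lat <- lapply(1:4, function(i)
      nn_conv2d(config$backbone_widths[i], Fc, k = 1L, pad = 0L))
    net$fpn_out <- lapply(1:4, function(i) nn_conv2d(Fc, Fc, k = 3L))
    sz <- config$input_size / c(4, 8, 16)
    net$ups <- lapply(1:3, function(i) nn_upsample(sz[i], sz[i]))
    net$p6pool <- nn_maxpool2()
    A <- length(config$anchor_ratios)
    net$rpn <- lapply(1:5, function(l) list(
      conv = nn_conv2d(Fc, Fc, k = 3L), relu = nn_relu(),
      cls = nn_conv2d(Fc, A, k = 1L, pad = 0L, init_gain = 0.1),
      box = nn_conv2d(Fc, 4L * A, k = 1L, pad = 0L, init_gain = 0.1)))
    net$anchors <- .make_anchors(config)
    rs <- config$roi_size
    net$roi7 <- lapply(1:3, function(i)
      nn_roi_align(c(rs, rs), 4L, aligned = fl$RA))
    net$fc1 <- nn_linear(rs * rs * Fc, config$fc_dim)
    net$fc_relu <- nn_relu()
    net$cls_fc <- nn_linear(config$fc_dim, 2L, init_gain = 0.1)
    net$box_fc <- nn_linear(config$fc_dim, 4L, init_gain = 0.1)
    hs <- config$head_size
    net$roi14 <- nn_roi_align(c(hs, hs), 4L, aligned = fl$RA)
    net$mconv1 <- nn_seq(nn_conv2d(Fc, Fc, k = 3L), nn_bn(Fc), nn_relu())
    net$mconv2 <- nn_seq(nn_conv2d(Fc, Fc, k = 3L), nn_bn(Fc), nn_relu())
    net$ma <- nn_mixed_attn(Fc, mode = config$attention_mode,
                            use_ca = fl$CA, use_sa = fl$SA)
    net$bpp <- if (fl$EA) nn_bpp(Fc, config$bpp) else NULL
    net$fuse <- if (fl$EA) nn_edge_fuse() else NULL
    net$mask_head <- nn_seq(nn_conv2d(Fc, Fc, k = 3L), nn_relu(),
                            nn_conv2d(Fc, 1L, k = 1L, pad = 0L))
    net$reg_conv <- if (fl$RS) nn_conv2d(Fc, 1L, k = 1L, pad = 0L) else NULL
  })
  net$params <- c(
    net$stem$params,
    do.call(c, lapply(net$stages, function(s) s$params)),
    do.call(c, lapply(net$lat, function(l) l$params)),
    do.call(c, lapply(net$fpn_out, function(l) l$params)),
    do.call(c, lapply(net$rpn, function(r)
      c(r$conv$params, r$cls$params, r$box$params))),
    net$fc1$params, net$cls_fc$params, net$box_fc$params,
    net$mconv1$params, net$mconv2$params, net$ma$params,
    if (!is.null(net$bpp)) net$bpp$params,
    net$mask_head$params,
    if (!is.null(net$reg_conv)) net$reg_conv$params)
  class(net) <- "ean_net"
  net
}

#' Census of live modules and trainable parameters
#'
#' @param net A \code{\link{build_ean}} network.
#' @return List: logical has_channel_attention, has_spatial_attention,
#'   has_bpp, has_region_head, aligned_roi; integer n_params.
#' @export
ean_module_census <- function(net) {
  list(has_channel_attention = isTRUE(net$config$flags$CA),
       has_spatial_attention = isTRUE(net$config$flags$SA),
       has_bpp = !is.null(net$bpp),
       has_region_head = !is.null(net$reg_conv),
       aligned_roi = isTRUE(net$config$flags$RA),
       n_params = n_trainable(net$params))
}

# Shared trunk: backbone stages + FPN + per-level RPN outputs.
.trunk_forward <- function(net, x, train = TRUE) {
  c1 <- net$stem$fwd(x, train)
  feats <- vector("list", 4)
  s <- c1
  for (i in 1:4) { s <- net$stages[[i]]$fwd(s, train); feats[[i]] <- s }
  l <- lapply(1:4, function(i) net$lat[[i]]$fwd(feats[[i]], train))
  m <- vector("list", 4)
  m[[4]] <- l[[4]]
  for (i in 3:1) m[[i]] <- l[[i]] + net$ups[[i]]$fwd(m[[i + 1]], train)
  P <- lapply(1:4, function(i) net$fpn_out[[i]]$fwd(m[[i]], train))
  P[[5]] <- net$p6pool$fwd(P[[4]], train)
  rpn <- lapply(1:5, function(li) {
    r <- net$rpn[[li]]
    h <- r$relu$fwd(r$conv$fwd(P[[li]], train), train)
    list(cls = r$cls$fwd(h, train), box = r$box$fwd(h, train))
  })
  list(P = P, rpn = rpn)
}

# Backward through FPN + backbone given per-level pyramid gradients
# (list dP, any entry may be NULL) and per-level RPN output gradients.
.trunk_backward <- function(net, dP, drpn) {
  for (li in 1:5) {
    g <- drpn[[li]]
    if (is.null(g)) next
    r <- net$rpn[[li]]
    dh <- 0
    if (!is.null(g$cls)) dh <- dh + r$cls$bwd(g$cls)
    if (!is.null(g$box)) dh <- dh + r$box$bwd(g$box)
    if (!is.atomic(dh) || length(dh) > 1) {
      add <- r$conv$bwd(r$relu$bwd(dh))
      dP[[li]] <- if (is.null(dP[[li]])) add else dP[[li]] + add
    }
  }
  if (!is.null(dP[[5]])) {
    add <- net$p6pool$bwd(dP[[5]])
    dP[[4]] <- if (is.null(dP[[4]])) add else dP[[4]] + add
  }
  dm <- vector("list", 4)
  for (i in 1:4)
    dm[[i]] <- if (is.null(dP[[i]])) NULL else net$fpn_out[[i]]$bwd(dP[[i]])
  # top-down chain m[i] = l[i] + up(m[i+1])
  dl <- vector("list", 4)
  for (i in 1:3) {
    if (is.null(dm[[i]])) next
    dl[[i]] <- dm[[i]]
    add <- net$ups[[i]]$bwd(dm[[i]])
    dm[[i + 1]] <- if (is.null(dm[[i + 1]])) add else dm[[i + 1]] + add
  }
  dl[[4]] <- dm[[4]]
  dfeat <- vector("list", 4)
  for (i in 1:4)
    dfeat[[i]] <- if (is.null(dl[[i]])) NULL else net$lat[[i]]$bwd(dl[[i]])
  dnext <- NULL
  for (i in 4:1) {
    dtot <- dfeat[[i]]
    if (!is.null(dnext)) dtot <- if (is.null(dtot)) dnext else dtot + dnext
    dnext <- if (is.null(dtot)) NULL else net$stages[[i]]$bwd(dtot)
  }
  if (!is.null(dnext)) net$stem$bwd(dnext)
  invisible(NULL)
}

# Continuous image coordinates -> feature-map coordinates at given stride
# (pixel centers at integers in both spaces; no rounding).
.box_to_feat <- function(box, stride) (box + 0.5) / stride - 0.5

# Mask/attention branch forward from P2 for one RoI box (feature coords).
.mask_branch_forward <- function(net, P2, box, train = TRUE) {
  f14 <- net$roi14$fwd(P2, box, train)
  Of <- net$mconv2$fwd(net$mconv1$fwd(f14, train), train)
  Z <- net$ma$fwd(Of, train)
  if (!is.null(net$bpp)) {
    Fp <- net$bpp$fwd(Z, train)
    Fe <- net$fuse$fwd(Z, Fp, train)
  } else {
    Fp <- NULL; Fe <- Z
  }
  mlog <- net$mask_head$fwd(Fe, train)
  mprob <- 1 / (1 + exp(-mlog))
  rprob <- if (!is.null(net$reg_conv)) {
    1 / (1 + exp(-net$reg_conv$fwd(Fe, train)))
  } else NULL
  list(Of = Of, Z = Z, Fp = Fp, Fe = Fe, mlog = mlog, mprob = mprob,
       rprob = rprob)
}

# Backward of the mask/attention branch; returns dP2 contribution.
# d_m: gradient wrt mask logits; d_r: wrt region logits (or NULL);
# d_p: external gradient wrt F_points (edge supervision; or NULL).
.mask_branch_backward <- function(net, mb, d_m, d_r = NULL, d_p = NULL) {
  dFe <- net$mask_head$bwd(d_m)
  if (!is.null(d_r)) dFe <- dFe + net$reg_conv$bwd(d_r)
  if (!is.null(net$bpp)) {
    df <- net$fuse$bwd(dFe)
    dZ <- df$d_tumor
    dFp <- df$d_points
    if (!is.null(d_p)) dFp <- dFp + d_p
    dZ <- dZ + net$bpp$bwd(dFp)
  } else {
    dZ <- dFe
  }
  dOf <- net$ma$bwd(dZ)
  d14 <- net$mconv1$bwd(net$mconv2$bwd(dOf))
  net$roi14$bwd(d14)
}

# Focal-loss gradient wrt the true-class probability rho.
.dfocal_drho <- function(rho, alpha, gamma) {
  rho <- clamp(rho, .EPS_PROB, 1 - .EPS_PROB)
  alpha * (gamma * (1 - rho)^(pmax(gamma - 1, 0)) * log(rho) - (1 - rho)^gamma / rho)
}

# Central-difference gradient of the distance-IoU box loss wrt the 4 deltas.
.dbox_ddeltas <- function(anchor, t, gt, lcfg, eps = 1e-4) {
  g <- numeric(4)
  for (i in 1:4) {
    tp <- t; tp[i] <- tp[i] + eps
    tm <- t; tm[i] <- tm[i] - eps
    bp <- .decode_box(anchor, tp); bm <- .decode_box(anchor, tm)
    lp <- if (bp[1] < bp[3] && bp[2] < bp[4]) box_loss(bp, gt, lcfg) else NA
    lm <- if (bm[1] < bm[3] && bm[2] < bm[4]) box_loss(bm, gt, lcfg) else NA
    g[i] <- if (is.na(lp) || is.na(lm)) 0 else (lp - lm) / (2 * eps)
  }
  g
}
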