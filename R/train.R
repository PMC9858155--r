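# Training: augmentation, configuration, the fitting loop, checkpoints.

#' Augment a phantom sample
#'
#' Random compose of isotropic scaling, crop-and-pad translation, rotation,
#' shear ("transforming"), horizontal/vertical flips and salt impulse noise.
#' The same geometric map is applied to image (bilinear resampling) and mask
#' (nearest neighbour); the forward affine is attached as
#' \code{attr(, "affine")} (2 x 3 matrix) so cached boundary key points can
#' be transported instead of recomputed. Setting every range to its neutral
#' value (\code{scale = c(1, 1)}, \code{angle = c(0, 0)}, \code{shift = 0},
#' \code{shear = 0}, \code{flip = FALSE}, \code{salt = 0}) yields the
#' identity exactly.
#'
#' @param sample A \code{phantom_sample} (or list with image and mask).
#' @param seed Optional seed; NULL draws from the current RNG stream.
#' @param scale Length-2 range of isotropic scale factors.
#' @param angle Length-2 rotation range in degrees.
#' @param shift Max |translation| as a fraction of the image side.
#' @param shear Max |shear| coefficient.
#' @param flip Logical; allow horizontal/vertical flips (p = 0.5 each).
#' @param salt Fraction of pixels replaced by impulse noise.
#' @param max_retries Resample attempts if the transform empties the mask.
#' @return Augmented \code{phantom_sample} with attr "affine".
#' @export
augment_sample <- function(sample, seed = NULL,
                           scale = c(0.9, 1.1), angle = c(-15, 15),
                           shift = 0.08, shear = 0.05, flip = TRUE,
                           salt = 0.005, max_retries = 3L) {
  run <- function() .augment_once(sample, scale, angle, shift, shear, flip, salt,
                                  max_retries)
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

.augment_once <- function(sample, scale, angle, shift, shear, flip, salt,
                          max_retries) {
  img <- sample$image; msk <- sample$mask
  n <- nrow(img)
  c0 <- (n - 1) / 2
  for (attempt in seq_len(max_retries + 1L)) {
    s <- stats::runif(1, scale[1], scale[2])
    th <- stats::runif(1, angle[1], angle[2]) * pi / 180
    sh <- if (shear > 0) stats::runif(1, -shear, shear) else 0
    tx <- if (shift > 0) stats::runif(1, -shift, shift) * n else 0
    ty <- if (shift > 0) stats::runif(1, -shift, shift) * n else 0
    fx <- if (flip) sample(c(1, -1), 1) else 1
    fy <- if (flip) sample(c(1, -1), 1) else 1
    L <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      matrix(c(1, 0, sh, 1), 2, 2) * s
    L <- diag(c(fx, fy)) %*% L
    M <- cbind(L, c(tx + c0 - L[1, 1] * c0 - L[1, 2] * c0,
                    ty + c0 - L[2, 1] * c0 - L[2, 2] * c0))
    Minv_L <- solve(L)
    xs <- rep(0:(n - 1), each = n)    # column-major over (y fastest)
    ys <- rep(0:(n - 1), times = n)
    sx <- Minv_L[1, 1] * (xs - M[1, 3]) + Minv_L[1, 2] * (ys - M[2, 3])
    sy <- Minv_L[2, 1] * (xs - M[1, 3]) + Minv_L[2, 2] * (ys - M[2, 3])
    im_out <- matrix(bilinear_interpolate(array(img, c(n, n, 1)), sx, sy)[, 1], n, n)
    out_of_range <- sx < -0.5 | sx > n - 0.5 | sy < -0.5 | sy > n - 0.5
    im_out[matrix(out_of_range, n, n)] <- 0
    rs <- round(sy); cs <- round(sx)
    ok <- rs >= 0 & rs < n & cs >= 0 & cs < n
    mv <- integer(n * n)
    mv[ok] <- msk[cbind(rs[ok] + 1L, cs[ok] + 1L)]
    m_out <- matrix(mv, n, n)
    if (sum(m_out) > 0) break
    if (attempt > max_retries) return(sample)   # logged-skip fallback
  }
  if (salt > 0) {
    npix <- round(salt * n * n)
    if (npix > 0) {
      at <- sample.int(n * n, npix)
      im_out[at] <- ifelse(stats::runif(npix) < 0.5, 0, 1)
    }
  }
  idx <- which(m_out == 1L, arr.ind = TRUE)
  out <- structure(list(image = clamp(im_out, 0, 1), mask = m_out,
                        meta = list(centroid = c(x = mean(idx[, 2]) - 1,
                                                 y = mean(idx[, 1]) - 1),
                                    area = nrow(idx),
                                    boundary_blur_sigma = sample$meta$boundary_blur_sigma,
                                    seed = sample$meta$seed)),
                   class = "phantom_sample")
  attr(out, "affine") <- M
  out
}

# Transport (x, y) points through a forward 2 x 3 affine.
.transform_points <- function(points, M) {
  if (is.null(points) || nrow(points) == 0) return(points)
  cbind(M[1, 1] * points[, 1] + M[1, 2] * points[, 2] + M[1, 3],
        M[2, 1] * points[, 1] + M[2, 2] * points[, 2] + M[2, 3])
}

#' Training configuration
#'
#' Reference-scale defaults (epochs 182, batch 16, learning rate 0.02,
#' momentum 0.9, weight decay 1e-4, 512 x 512 inputs) require accelerator
#' hardware; \code{tiny_mode} switches to the CPU-feasible preset used
#' throughout the tests (batch 4, AdamW at 2e-3, short boundary key-point
#' search per training image).
#'
#' @param epochs Training epochs.
#' @param batch_size Images per optimizer step (gradients are accumulated).
#' @param learning_rate Initial learning rate.
#' @param momentum SGD momentum (also Adam beta1).
#' @param weight_decay Decoupled weight decay coefficient.
#' @param optimizer "adamw" (default) or "sgd".
#' @param augment Logical; apply the augmentation pipeline.
#' @param seed Master seed for data order, augmentation and initialization.
#' @param tiny_mode Logical; apply the CPU preset.
#' @param bkps_n,bkps_T,bkps_seed Key-point count, search budget and seed
#'   for the per-image supervision targets (cached, content-addressed).
#' @param early_stop_dsc Stop when validation DSC reaches this value (NULL
#'   disables).
#' @param val_every Validate every k epochs (when validation data given).
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(epochs = 182L, batch_size = 16L,
                         learning_rate = 0.02, momentum = 0.9,
                         weight_decay = 1e-4,
                         optimizer = c("adamw", "sgd"),
                         augment = TRUE, seed = 1L, tiny_mode = FALSE,
                         bkps_n = 20L, bkps_T = 3000L, bkps_seed = 99L,
                         early_stop_dsc = NULL, val_every = 1L) {
  optimizer <- match.arg(optimizer)
  if (tiny_mode) {
    if (missing(batch_size)) batch_size <- 4L
    if (missing(learning_rate)) learning_rate <- 2e-3
    if (missing(bkps_T)) bkps_T <- 30L
    if (missing(epochs)) epochs <- 12L
  }
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            weight_decay >= 0, bkps_n >= 3, bkps_T >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, optimizer = optimizer,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 tiny_mode = isTRUE(tiny_mode),
                 bkps_n = as.integer(bkps_n), bkps_T = as.integer(bkps_T),
                 bkps_seed = as.integer(bkps_seed),
                 early_stop_dsc = early_stop_dsc,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

# Collect batch-norm layers (for checkpointing running statistics).
.find_bn <- function(x, seen = new.env()) {
  out <- list()
  scan <- function(o) {
    if (is.environment(o)) {
      key <- format(o)
      if (!is.null(seen[[key]])) return()
      seen[[key]] <- TRUE
      if (!is.null(o$run_mean)) { out[[length(out) + 1]] <<- o; return() }
      for (nm in ls(o)) if (nm %in% c("layers", "branches", "stages", "lat",
                                      "fpn_out", "rpn", "ups", "roi7", "stem",
                                      "mconv1", "mconv2", "ma", "ca", "sa",
                                      "bpp", "mask_head", "proj", "c1", "c2",
                                      "n1", "n2", "p6pool", "reg_conv"))
        scan(o[[nm]])
    } else if (is.list(o)) for (e in o) scan(e)
  }
  scan(x)
  out
}

# Per-image supervision targets with content-addressed caching.
.bkps_target <- function(cache, image, mask, n, T, seed) {
  key <- content_key(image, mask, n, T, seed)
  hit <- cache$store[[key]]
  if (!is.null(hit)) { cache$hits <- cache$hits + 1L; return(hit) }
  cache$misses <- cache$misses + 1L
  kp <- select_boundary_keypoints(image, mask, n = n, T = T, seed = seed)$P_select
  cache$store[[key]] <- kp
  kp
}

#' Fit the edge-attention segmentation network
#'
#' Optimizes the total objective (classification + box + mask + edge +
#' region losses) with gradient accumulation over \code{batch_size} images.
#' Boundary key-point supervision targets are computed once per training
#' image by the randomized selection search and cached (content-addressed);
#' under augmentation the cached key points are transported through the
#' sample's affine rather than recomputed. Fixed seeds give bitwise
#' reproducible runs on CPU.
#'
#' @param train_samples List of \code{phantom_sample}s (image + mask).
#' @param val_samples Optional held-out list for per-epoch DSC.
#' @param net_config A \code{\link{ean_config}}.
#' @param config A \code{\link{train_config}}.
#' @param checkpoint_dir Optional directory; a resumable checkpoint is
#'   written after every epoch.
#' @param resume Optional path to a checkpoint written by a previous run
#'   with identical configurations; training continues from its epoch.
#' @param verbose Print one line per epoch.
#' @return Object of class \code{ean_model}: the fitted network plus
#'   configurations and a per-epoch \code{history} data.frame.
#' @export
ean_train <- function(train_samples, val_samples = NULL,
                       net_config = ean_config(tiny = TRUE),
                       config = train_config(tiny_mode = TRUE),
                       checkpoint_dir = NULL, resume = NULL,
                       verbose = TRUE) {
  stopifnot(length(train_samples) >= 1)
  set.seed(config$seed)
  net <- build_ean(net_config)
  bn_layers <- .find_bn(net)
  opt <- make_optimizer(net$params, kind = config$optimizer,
                        lr = config$learning_rate, momentum = config$momentum,
                        weight_decay = config$weight_decay)
  cache <- new.env(); cache$store <- new.env(parent = emptyenv())
  cache$hits <- 0L; cache$misses <- 0L
  history <- list()
  start_epoch <- 1L
  if (!is.null(resume)) {
    ck <- readRDS(resume)
    params_restore(net$params, ck$snapshot)
    for (i in seq_along(bn_layers)) {
      bn_layers[[i]]$run_mean <- ck$bn[[i]]$mean
      bn_layers[[i]]$run_var <- ck$bn[[i]]$var
    }
    opt$state$t <- ck$opt_t
    assign(".Random.seed", ck$rng, envir = globalenv())
    history <- ck$history
    start_epoch <- ck$epoch + 1L
  }
  lcfg <- loss_config()
  fl <- net_config$flags
  n_tr <- length(train_samples)
  # precompute key-point targets on the un-augmented images
  kps <- vector("list", n_tr)
  if (fl$ES) {
    for (i in seq_len(n_tr))
      kps[[i]] <- .bkps_target(cache, train_samples[[i]]$image,
                               train_samples[[i]]$mask,
                               config$bkps_n, config$bkps_T, config$bkps_seed)
  }
  t_start <- Sys.time()
  for (ep in start_epoch:config$epochs) {
    ord <- sample.int(n_tr)
    acc <- c(l_cls = 0, l_box = 0, l_mask = 0, l_edge = 0, l_reg = 0,
             l_total = 0)
    in_batch <- 0L
    for (i in ord) {
      smp <- train_samples[[i]]
      kp <- kps[[i]]
      if (config$augment) {
        aug <- augment_sample(smp)
        M <- attr(aug, "affine")
        if (!is.null(M) && !is.null(kp)) kp <- .transform_points(kp, M)
        smp <- aug
      }
      # step-internal stochastic choices (RoI jitter, negative RoIs) come
      # from a per-sample substream, so a frozen model yields an identical
      # loss trace every epoch while augmentation stays epoch-varying
      step_seed <- (config$seed * 131L + i * 7919L) %% 21474830L
      b <- with_local_seed(step_seed,
                           .train_step(net, smp$image, smp$mask, kp, lcfg))
      if (!is.finite(b$l_total)) {
        bad <- names(Filter(function(v) !is.finite(v),
                            unclass(b)[c("l_cls", "l_box", "l_mask",
                                         "l_edge", "l_reg")]))
        stop(sprintf("training diverged (non-finite %s) at epoch %d",
                     paste(bad, collapse = ","), ep))
      }
      acc <- acc + unlist(b[names(acc)])
      in_batch <- in_batch + 1L
      if (in_batch >= config$batch_size) { opt$step(); in_batch <- 0L }
    }
    if (in_batch > 0L) opt$step()
    acc <- acc / n_tr
    val_dsc <- NA_real_
    if (!is.null(val_samples) && (ep %% config$val_every == 0L ||
                                  ep == config$epochs)) {
      dscs <- vapply(val_samples, function(v) {
        o <- ean_forward(net, v$image)
        d <- overlap_coefficients((o$mask > 0.5) * 1L, v$mask)$DSC
        if (is.na(d)) 0 else d
      }, 0)
      val_dsc <- mean(dscs)
    }
    history[[length(history) + 1]] <- data.frame(
      epoch = ep, t(acc), val_dsc = val_dsc,
      elapsed = as.numeric(Sys.time() - t_start, units = "secs"))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f (mask %.4f edge %.4f reg %.4f)%s\n",
                  ep, acc["l_total"], acc["l_mask"], acc["l_edge"],
                  acc["l_reg"],
                  if (is.na(val_dsc)) "" else sprintf("  val DSC %.4f", val_dsc)))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(snapshot = params_snapshot(net$params),
                   bn = lapply(bn_layers, function(b)
                     list(mean = b$run_mean, var = b$run_var)),
                   opt_t = opt$state$t, epoch = ep,
                   rng = get(".Random.seed", envir = globalenv()),
                   history = history),
              file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
    if (!is.null(config$early_stop_dsc) && !is.na(val_dsc) &&
        val_dsc >= config$early_stop_dsc) break
  }
  structure(list(net = net, net_config = net_config, train_config = config,
                 history = do.call(rbind, history),
                 bkps_cache = list(hits = cache$hits, misses = cache$misses)),
            class = "ean_model")
}

#' @export
print.ean_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("edge-attention segmentation model: %dx%d input, %d parameters, %d epoch(s)\n",
              x$net_config$input_size, x$net_config$input_size,
              n_trainable(x$net$params), nrow(h)))
  last <- h[nrow(h), ]
  cat(sprintf("  final loss %.4f%s\n", last$l_total,
              if (is.na(last$val_dsc)) "" else
                sprintf(", validation DSC %.4f", last$val_dsc)))
  fl <- x$net_config$flags
  cat(sprintf("  modules: RA=%s CA=%s SA=%s EA=%s ES=%s RS=%s (%s attention)\n",
              fl$RA, fl$CA, fl$SA, fl$EA, fl$ES, fl$RS,
              x$net_config$attention_mode))
  invisible(x)
}

#' @export
summary.ean_model <- function(object, ...) {
  print(object)
  cat("\nper-epoch history (tail):\n")
  print(utils::tail(object$history[, c("epoch", "l_cls", "l_box", "l_mask",
                                       "l_edge", "l_reg", "l_total",
                                       "val_dsc")], 5), row.names = FALSE)
  invisible(object$history)
}

#' Predict a segmentation for new images
#'
#' @param object A fitted \code{ean_model}.
#' @param newdata A matrix, a \code{phantom_sample}, or a list of either.
#' @param type "mask" (binary, default), "prob" (probability map) or
#'   "output" (full \code{ean_output}).
#' @param threshold Binarization threshold (default 0.5).
#' @param ... Unused.
#' @return Single result or list of results matching \code{newdata}.
#' @export
predict.ean_model <- function(object, newdata, type = c("mask", "prob", "output"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(x) {
    img <- if (is.list(x)) x$image else x
    o <- ean_forward(object$net, img)
    switch(type,
           mask = (o$mask > threshold) * 1L,
           prob = o$mask,
           output = o)
  }
  if (is.matrix(newdata) || inherits(newdata, "phantom_sample")) one(newdata)
  else lapply(newdata, one)
}

#' @export
plot.ean_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$l_total, type = "b", xlab = "epoch",
                 ylab = "mean total loss", main = "training loss", ...)
  if (any(!is.na(h$val_dsc)))
    graphics::plot(h$epoch, h$val_dsc, type = "b", xlab = "epoch",
                   ylab = "validation DSC", main = "validation overlap",
                   ylim = c(0, 1))
  else graphics::plot.new()
  invisible(x)
}

#' Evaluate a fitted model on a sample set
#'
#' Per-image confusion metrics at threshold 0.5, reported as the average
#' over images (headline) alongside the pooled-count variant.
#'
#' @param model A fitted \code{ean_model}.
#' @param samples List of samples with image and mask.
#' @return List with \code{per_image} (data.frame), \code{mean} (averaged
#'   metrics) and \code{pooled} (metrics of summed counts).
#' @export
ean_evaluate <- function(model, samples) {
  rows <- lapply(samples, function(s) {
    pm <- predict(model, s, type = "mask")
    cc <- confusion_counts(pm, s$mask)
    m <- seg_metrics(cc)
    data.frame(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               Acc = m$Acc, Pre = m$Pre, Re = m$Re, F1 = m$F1,
               IOU = m$IOU, DSC = m$DSC)
  })
  per <- do.call(rbind, rows)
  pooled_counts <- structure(list(TP = sum(per$TP), TN = sum(per$TN),
                                  FP = sum(per$FP), FN = sum(per$FN)),
                             class = "confusion_counts")
  list(per_image = per,
       mean = colMeans(per[, c("Acc", "Pre", "Re", "F1", "IOU", "DSC")],
                       na.rm = TRUE),
       pooled = seg_metrics(pooled_counts))
}

#' Ablation harness over module flags
#'
#' Trains one tiny model per flag row and seed on freshly generated
#' phantoms and reports mean and sd of the evaluation metrics per row, in
#' the given row order.
#'
#' @param rows Named list of flag lists (each as in
#'   \code{\link{ean_config}}).
#' @param seeds Integer vector of training seeds (>= 1).
#' @param n_train,n_test Phantoms per run.
#' @param epochs Epochs per run.
#' @param attention_mode Attention wiring for all rows.
#' @param csv Optional path; per-row summary written as CSV.
#' @return data.frame with one row per flag row: mean and sd of DSC / IOU
#'   (and Acc, Pre, Re, F1) over seeds.
#' @export
run_ablation <- function(rows, seeds = 1:3, n_train = 60L, n_test = 20L,
                         epochs = 6L, attention_mode = "parallel",
                         csv = NULL) {
  res <- list()
  for (rn in names(rows)) {
    per_seed <- list()
    for (sd in seeds) {
      dat <- make_phantom_set(n_train + n_test, base_seed = 1000L + sd)
      tr <- dat[seq_len(n_train)]
      te <- dat[n_train + seq_len(n_test)]
      ncfg <- ean_config(tiny = TRUE, flags = rows[[rn]],
                          attention_mode = attention_mode, seed = sd)
      tcfg <- train_config(tiny_mode = TRUE, epochs = epochs, seed = sd,
                           augment = FALSE)
      fit <- ean_train(tr, val_samples = NULL, net_config = ncfg,
                        config = tcfg, verbose = FALSE)
      ev <- ean_evaluate(fit, te)
      per_seed[[length(per_seed) + 1]] <- ev$mean
    }
    M <- do.call(rbind, per_seed)
    res[[rn]] <- data.frame(row = rn,
                            t(colMeans(M)),
                            t(stats::setNames(apply(M, 2, stats::sd),
                                              paste0(colnames(M), "_sd"))))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Generate a list of tiny phantoms for training/evaluation
#'
#' Convenience wrapper producing 64 x 64 phantoms with the default tiny
#' study conditions (lesion radius 10-18 px, rim blur sigma 1.5 px, 3
#' distractor ellipses, 2% Gaussian noise, 0.2% salt).
#'
#' @param n Number of samples.
#' @param base_seed Seed of the first sample; sample i uses base_seed+i-1.
#' @param image_size Image side (default 64).
#' @return List of \code{phantom_sample}s.
#' @export
make_phantom_set <- function(n, base_seed = 1L, image_size = 64L) {
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_config(
      image_size = image_size,
      lesion_radius_range = c(image_size * 0.16, image_size * 0.28),
      boundary_blur_sigma = 1.5, n_distractors = 3L,
      noise_sigma = 0.02, salt_fraction = 0.002,
      seed = base_seed + i - 1L))
  })
}
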