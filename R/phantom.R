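#' Configuration for synthetic fuzzy-boundary lesion phantoms
#'
#' A phantom emulates the imaging regime the segmentation method targets: a
#' single bright lesion whose rim intensity is smoothed (the "fuzzy
#' boundary"), surrounded by tissue-like distractor ellipses whose
#' intensities overlap the lesion's, with additive Gaussian and salt-impulse
#' noise applied last. The ground-truth mask records the crisp pre-blur
#' lesion support, so the ambiguity lives in the intensities, never in the
#' label.
#'
#' @param image_size Side of the square image in pixels (default 512; use 64
#'   for desk-scale work).
#' @param lesion_radius_range Numeric length-2, min and max base radius of
#'   the lesion in pixels. The maximum perturbed radius must fit inside the
#'   image with a 2-pixel margin.
#' @param boundary_blur_sigma Gaussian sigma (pixels) used to smooth the
#'   lesion rim intensity step; 0 gives a crisp step.
#' @param n_distractors Number of background ellipses with intensities
#'   overlapping the lesion's, placed outside the lesion support.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise, as a fraction of full scale, in [0, 1].
#' @param salt_fraction Fraction of pixels replaced by impulse (salt/pepper)
#'   noise, in [0, 0.05].
#' @param seed Integer seed; fixed seed gives bitwise-identical phantoms.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = 512L,
                           lesion_radius_range = c(image_size / 12, image_size / 4.5),
                           boundary_blur_sigma = image_size / 170,
                           n_distractors = 6L,
                           noise_sigma = 0.03,
                           salt_fraction = 0.005,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(lesion_radius_range) == 2)
  if (image_size < 8) stop("image_size too small")
  if (any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop("lesion_radius_range must be positive and ordered (min, max)")
  if (lesion_radius_range[2] >= image_size / 2)
    stop("lesion_radius_range max must be < image_size / 2")
  if (boundary_blur_sigma < 0) stop("boundary_blur_sigma must be >= 0")
  if (noise_sigma < 0 || noise_sigma > 1) stop("noise_sigma must be in [0, 1]")
  if (salt_fraction < 0 || salt_fraction > 0.05)
    stop("salt_fraction must be in [0, 0.05]")
  structure(list(image_size = image_size,
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 boundary_blur_sigma = as.numeric(boundary_blur_sigma),
                 n_distractors = as.integer(n_distractors),
                 noise_sigma = as.numeric(noise_sigma),
                 salt_fraction = as.numeric(salt_fraction),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Intensity levels of the phantom scene. Distractor intensities deliberately
# overlap the lesion's so brightness alone cannot separate lesion from
# background structures.
.phantom_levels <- list(background = 0.15, lesion = 0.85,
                        distractor = c(0.40, 0.90))

# Star-convex radius profile: r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)).
# Low-order harmonics keep the boundary simple and closed; total relative
# perturbation is capped at 0.25 so the blob stays star-convex about its
# center and fits the feasibility margin.
.sample_radius_profile <- function(r0) {
  k <- 2:5
  amp <- stats::runif(length(k), 0, 0.15) / (k - 1)
  s <- sum(amp)
  if (s > 0.25) amp <- amp * (0.25 / s)
  phase <- stats::runif(length(k), 0, 2 * pi)
  function(theta) {
    pert <- rep(0, length(theta))
    for (i in seq_along(k)) pert <- pert + amp[i] * cos(k[i] * theta + phase[i])
    r0 * (1 + pert)
  }
}

#' Generate one synthetic lesion phantom
#'
#' The lesion is a star-convex blob (random low-order radial Fourier
#' perturbation of a disk). The image is composed as background +
#' distractor ellipses (outside the lesion) + the lesion intensity step,
#' where only the lesion step is Gaussian-blurred, then Gaussian and salt
#' noise are applied. The mask is the crisp pre-blur support and always has
#' exactly one connected foreground component.
#'
#' @param config A \code{\link{phantom_config}}.
#' @return An object of class \code{phantom_sample}: list with \code{image}
#'   (matrix in [0,1]), \code{mask} (0/1 integer matrix), and \code{meta}
#'   (lesion centroid in 0-based (x, y), area in pixels, blur sigma, seed).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  rmax_pert <- config$lesion_radius_range[2] * 1.25
  if (2 * (rmax_pert + 2) > n)
    stop("lesion cannot fit inside the image with a 2-pixel margin")
  with_local_seed(config$seed, {
    r0 <- stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
    rfun <- .sample_radius_profile(r0)
    rmax <- r0 * 1.25
    lo <- rmax + 2; hi <- (n - 1) - rmax - 2
    cx <- stats::runif(1, lo, hi)
    cy <- stats::runif(1, lo, hi)

    xs <- matrix(rep(0:(n - 1), each = n), n, n)   # [r, c] -> x = c - 1
    ys <- matrix(rep(0:(n - 1), times = n), n, n)  # [r, c] -> y = r - 1
    dx <- xs - cx; dy <- ys - cy
    theta <- atan2(dy, dx)
    mask <- (dx^2 + dy^2) <= rfun(theta)^2
    storage.mode(mask) <- "integer"

    lv <- .phantom_levels
    bg <- matrix(lv$background, n, n)
    for (i in seq_len(config$n_distractors)) {
      ec <- stats::runif(2, 0, n - 1)
      ax <- stats::runif(2, n / 40, n / 8)
      ang <- stats::runif(1, 0, pi)
      val <- stats::runif(1, lv$distractor[1], lv$distractor[2])
      u <- (xs - ec[1]) * cos(ang) + (ys - ec[2]) * sin(ang)
      v <- -(xs - ec[1]) * sin(ang) + (ys - ec[2]) * cos(ang)
      inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
      bg[inside & mask == 0L] <- val
    }

    delta <- mask * (lv$lesion - lv$background)
    delta_blur <- if (config$boundary_blur_sigma > 0)
      blur_gaussian(delta, config$boundary_blur_sigma) else delta
    img <- bg * (mask == 0L) + lv$background * (mask == 1L) + delta_blur

    if (config$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
    if (config$salt_fraction > 0) {
      npix <- round(config$salt_fraction * n * n)
      if (npix > 0) {
        at <- sample.int(n * n, npix)
        img[at] <- ifelse(stats::runif(npix) < 0.5, 0, 1)
      }
    }
    img <- clamp(img, 0, 1)

    idx <- which(mask == 1L, arr.ind = TRUE)
    meta <- list(centroid = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
                 area = nrow(idx),
                 boundary_blur_sigma = config$boundary_blur_sigma,
                 seed = config$seed)
    structure(list(image = img, mask = mask, meta = meta),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %dx%d image, lesion area %d px, centroid (%.1f, %.1f)\n",
              nrow(x$image), ncol(x$image), x$meta$area,
              x$meta$centroid[1], x$meta$centroid[2]))
  invisible(x)
}

#' @export
plot.phantom_sample <- function(x, show_mask = TRUE, ...) {
  op <- graphics::par(mfrow = if (show_mask) c(1, 2) else c(1, 1),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  show(x$image, "image")
  if (show_mask) show(x$mask, "mask")
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Emits \code{n_samples} 8-bit grayscale image PNGs, matching mask PNGs
#' (values exactly 0 and 255), and a JSON manifest listing the pairs, their
#' seeds and the generating configuration. Sample i is generated with seed
#' \code{config$seed + i - 1}.
#'
#' @param n_samples Number of image/mask pairs.
#' @param out_dir Output directory (created if absent).
#' @param config A \code{\link{phantom_config}}; its seed is the base seed.
#' @param force Overwrite an existing manifest (default FALSE).
#' @return Path to the written manifest (invisibly the manifest list as an
#'   attribute).
#' @export
write_phantom_dataset <- function(n_samples, out_dir, config, force = FALSE) {
  stopifnot(inherits(config, "phantom_config"), n_samples >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists; use force = TRUE to overwrite")
  pairs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg_i <- config; cfg_i$seed <- config$seed + i - 1L
    s <- generate_phantom(cfg_i)
    img_file <- sprintf("image_%04d.png", i)
    mask_file <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(out_dir, img_file))
    png::writePNG(s$mask * 1.0, file.path(out_dir, mask_file))
    pairs[[i]] <- list(image = img_file, mask = mask_file, seed = cfg_i$seed)
  }
  manifest <- list(pairs = pairs, config = unclass(config))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(structure(manifest_path, manifest = manifest))
  manifest_path
}

#' Read a phantom dataset written by \code{\link{write_phantom_dataset}}
#'
#' @param manifest_path Path to the JSON manifest.
#' @return List of \code{phantom_sample}-like lists (image in [0,1], 0/1
#'   integer mask, seed in meta).
#' @export
read_phantom_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  lapply(man$pairs, function(p) {
    img <- png::readPNG(file.path(dir, p$image))
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(file.path(dir, p$mask))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    msk <- (msk > 0.5) * 1L
    storage.mode(msk) <- "integer"
    structure(list(image = img, mask = msk, meta = list(seed = p$seed)),
              class = "phantom_sample")
  })
}
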