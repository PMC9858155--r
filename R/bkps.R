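# Boundary key points selection (BKPS): candidate edge extraction, region
# construction from points, the 95th-percentile Hausdorff distance, the
# randomized selection search, and rasterization of the selected points into
# the supervision target for the BPP head.

# --- Canny edge detection ---------------------------------------------------
# No installed R package provides Canny, so it is implemented here:
# Gaussian smoothing, Sobel gradients, 4-direction non-maximum suppression,
# and hysteresis with thresholds derived from Otsu's criterion on the
# gradient magnitude (high = Otsu, low = 0.4 * high).

.otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (!length(v) || max(v) <= min(v)) return(ifelse(length(v), max(v), 0))
  h <- tabulate(pmin(nbins, 1L + floor((v - min(v)) / (max(v) - min(v)) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  min(v) + (k / nbins) * (max(v) - min(v))
}

canny_edges <- function(image, sigma = 1.0) {
  img <- blur_gaussian(image, sigma)
  H <- nrow(img); W <- ncol(img)
  pad <- rbind(img[1, ], img, img[H, ])
  pad <- cbind(pad[, 1], pad, pad[, W])
  sub <- function(dr, dc) pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  # quantize direction to 0, 45, 90, 135 degrees
  sector <- floor(((ang + pi) / pi * 4 + 0.5)) %% 4
  magp <- rbind(0, cbind(0, mag, 0), 0)
  at <- function(dr, dc) magp[2:(H + 1) + dr, 2:(W + 1) + dc]
  n1 <- at(0, 1) * (sector == 0) + at(1, 1) * (sector == 1) +
    at(1, 0) * (sector == 2) + at(1, -1) * (sector == 3)
  n2 <- at(0, -1) * (sector == 0) + at(-1, -1) * (sector == 1) +
    at(-1, 0) * (sector == 2) + at(-1, 1) * (sector == 3)
  nms <- mag * (mag >= n1 & mag >= n2)
  hi <- .otsu_threshold(nms[nms > 0])
  if (!is.finite(hi) || hi <= 0) return(matrix(FALSE, H, W))  # featureless image
  lo <- 0.4 * hi
  strong <- nms >= hi
  weak <- nms >= lo & !strong
  # hysteresis: grow strong through weak (8-connectivity)
  lab <- strong
  repeat {
    labp <- matrix(FALSE, H + 2, W + 2)
    labp[2:(H + 1), 2:(W + 1)] <- lab
    grow <- weak & (labp[1:H, 1:W] | labp[1:H, 2:(W + 1)] | labp[1:H, 3:(W + 2)] |
                      labp[2:(H + 1), 1:W] | labp[2:(H + 1), 3:(W + 2)] |
                      labp[3:(H + 2), 1:W] | labp[3:(H + 2), 2:(W + 1)] |
                      labp[3:(H + 2), 3:(W + 2)]) & !lab
    if (!any(grow)) break
    lab <- lab | grow
  }
  lab
}

#' Candidate boundary pixels for key-point selection
#'
#' Runs Canny edge detection on the intensity image and keeps edge pixels
#' lying within \code{band_px} of the ground-truth mask contour. If fewer
#' than \code{3 * n} candidates survive (e.g. a featureless image), the
#' pool falls back to the mask contour pixels themselves.
#'
#' @param image Grayscale intensity matrix in [0, 1].
#' @param gt_mask Binary ground-truth mask (same shape), nonempty.
#' @param n Number of key points the downstream search will draw (sets the
#'   fallback threshold 3n). Default 20.
#' @param band_px Half-width in pixels of the band around the ground-truth
#'   contour (default 5).
#' @param sigma Gaussian sigma for the Canny smoothing (default 1).
#' @return m x 2 matrix of 0-based (x, y) candidate coordinates.
#' @export
extract_edge_pixels <- function(image, gt_mask, n = 20L, band_px = 5,
                                sigma = 1.0) {
  if (!any(gt_mask > 0)) stop("empty ground-truth mask")
  stopifnot(all(dim(image) == dim(gt_mask)))
  contour <- mask_contour_points(gt_mask)
  edges <- canny_edges(image, sigma)
  idx <- which(edges, arr.ind = TRUE)
  pool <- NULL
  if (nrow(idx) > 0) {
    pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    d2 <- .min_dist2(pts, contour)
    pool <- pts[d2 <= band_px^2 + 1e-9, , drop = FALSE]
  }
  if (is.null(pool) || nrow(pool) < 3 * n) pool <- contour
  pool
}

# Squared distance from each row of A to its nearest row of B.
.min_dist2 <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow(A), nrow(B))
  apply(d2, 1, min)
}

#' Construct a filled region from boundary points
#'
#' Orders the points by polar angle about their centroid (ties broken by
#' radius, nearer first), joins them into a simple polygon, and rasterizes
#' it: a pixel belongs to the region if its center is inside the polygon or
#' on its boundary. Note that for large point counts on non-convex shapes
#' the angular ordering can cut off narrow necks of the true region — this
#' is an inherent failure mode of connecting points in angle order.
#'
#' @param points m x 2 matrix of (x, y) coordinates, m >= 3, not all
#'   collinear.
#' @param shape Integer (H, W) of the output grid.
#' @return Object of class \code{region_mask}: list with \code{values}
#'   (H x W 0/1 matrix) and \code{boundary} (contour points, n x 2, 0-based
#'   (x, y)).
#' @export
construct_region <- function(points, shape) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  cx <- mean(points[, 1]); cy <- mean(points[, 2])
  ang <- atan2(points[, 2] - cy, points[, 1] - cx)
  rad <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
  ord <- order(ang, rad)
  P <- points[ord, , drop = FALSE]
  # collinearity: all cross products of consecutive edge vectors ~ 0
  v <- diff(rbind(P, P[1, , drop = FALSE]))
  cr <- v[-nrow(v), 1] * v[-1, 2] - v[-nrow(v), 2] * v[-1, 1]
  if (all(abs(cr) < 1e-9)) stop("degenerate polygon: points are collinear")
  H <- shape[1]; W <- shape[2]
  vals <- matrix(0L, H, W)
  x1 <- max(0L, floor(min(P[, 1]))); x2 <- min(W - 1L, ceiling(max(P[, 1])))
  y1 <- max(0L, floor(min(P[, 2]))); y2 <- min(H - 1L, ceiling(max(P[, 2])))
  if (x2 >= x1 && y2 >= y1) {
    px <- rep(x1:x2, each = y2 - y1 + 1)
    py <- rep(y1:y2, times = x2 - x1 + 1)
    inside <- rep(FALSE, length(px))
    on_edge <- rep(FALSE, length(px))
    m <- nrow(P)
    for (i in seq_len(m)) {
      a <- P[i, ]; b <- P[if (i == m) 1 else i + 1, ]
      crosses <- (a[2] > py) != (b[2] > py)
      if (any(crosses)) {
        xint <- (b[1] - a[1]) * (py - a[2]) / (b[2] - a[2]) + a[1]
        inside <- xor(inside, crosses & (px < xint))
      }
      # distance from pixel center to segment ab
      ab <- b - a
      L2 <- sum(ab^2)
      tt <- if (L2 > 0) clamp(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / L2, 0, 1) else 0
      dx <- px - (a[1] + tt * ab[1]); dy <- py - (a[2] + tt * ab[2])
      on_edge <- on_edge | (dx^2 + dy^2 < 1e-12)
    }
    keep <- inside | on_edge
    vals[cbind(py[keep] + 1L, px[keep] + 1L)] <- 1L
  }
  structure(list(values = vals, boundary = mask_contour_points(vals)),
            class = "region_mask")
}

#' 95th-percentile Hausdorff distance between two boundary point sets
#'
#' For each point of X the distance to its nearest point of Y is computed;
#' the directed distance d_XY is the 95th percentile (linear-interpolation
#' convention) of those minima, suppressing outliers. The result is the
#' maximum of the two directed distances, scaled by the pixel spacing.
#'
#' @param X,Y Nonempty m x 2 matrices of (x, y) points (pixel units).
#' @param spacing Physical size of a pixel in mm (default 1).
#' @param q Retained quantile of the directed distances (default 0.95).
#' @return Object of class \code{hd_result}: list with \code{hd},
#'   \code{d_xy}, \code{d_yx} (mm) and \code{spacing}.
#' @export
hausdorff95 <- function(X, Y, spacing = 1.0, q = 0.95) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("point sets must be nonempty")
  d2 <- outer(X[, 1], Y[, 1], `-`)^2 + outer(X[, 2], Y[, 2], `-`)^2
  d_xy <- stats::quantile(sqrt(apply(d2, 1, min)), q, names = FALSE, type = 7)
  d_yx <- stats::quantile(sqrt(apply(d2, 2, min)), q, names = FALSE, type = 7)
  structure(list(hd = max(d_xy, d_yx) * spacing,
                 d_xy = d_xy * spacing, d_yx = d_yx * spacing,
                 spacing = spacing),
            class = "hd_result")
}

#' @export
print.hd_result <- function(x, ...) {
  cat(sprintf("HD95 = %.3f mm (d_xy = %.3f, d_yx = %.3f, spacing %.3g mm/px)\n",
              x$hd, x$d_xy, x$d_yx, x$spacing))
  invisible(x)
}

#' Randomized boundary key-point selection
#'
#' Runs T iterations of: draw n distinct candidates uniformly without
#' replacement from the pool, construct the polygon region they bound,
#' measure its boundary's 95th-percentile Hausdorff distance to the
#' ground-truth contour, and keep the arg-min. Iterations whose sampled
#' points are degenerate (collinear) are skipped but still consume budget,
#' keeping runs comparable across seeds.
#'
#' @param image Intensity matrix (used for Canny candidates; ignored when
#'   \code{pool} is supplied).
#' @param gt_mask Binary ground-truth mask.
#' @param n Number of key points (default 20).
#' @param T Iteration budget (default 3000).
#' @param seed RNG seed.
#' @param spacing mm per pixel (default 1).
#' @param band_px Candidate band half-width (default 5).
#' @param pool Optional explicit m x 2 candidate matrix overriding edge
#'   extraction.
#' @return Object of class \code{bkps_run}: \code{P_select} (n x 2),
#'   \code{HD_min} (mm), \code{hd_trace} (best-so-far per iteration,
#'   non-increasing), \code{n}, \code{T}, \code{seed}, \code{n_degenerate}.
#' @export
select_boundary_keypoints <- function(image, gt_mask, n = 20L, T = 3000L,
                                      seed = 1L, spacing = 1.0, band_px = 5,
                                      pool = NULL) {
  if (is.null(pool))
    pool <- extract_edge_pixels(image, gt_mask, n = n, band_px = band_px)
  pool <- unique(as.matrix(pool))
  if (nrow(pool) < n)
    stop(sprintf("candidate pool (%d) smaller than n = %d", nrow(pool), n))
  Y <- mask_contour_points(gt_mask)
  shape <- dim(gt_mask)
  best <- NULL; hd_min <- Inf
  trace <- numeric(T)
  ndeg <- 0L
  with_local_seed(seed, {
    for (t in seq_len(T)) {
      pts <- pool[sample.int(nrow(pool), n), , drop = FALSE]
      hd_t <- tryCatch({
        reg <- construct_region(pts, shape)
        if (nrow(reg$boundary) == 0) stop("empty region")
        hausdorff95(reg$boundary, Y, spacing = spacing)$hd
      }, error = function(e) NA_real_)
      if (is.na(hd_t)) {
        ndeg <- ndeg + 1L
      } else if (hd_t < hd_min) {
        hd_min <- hd_t; best <- pts
      }
      trace[t] <- hd_min
    }
  })
  if (is.null(best)) stop("no non-degenerate iteration produced a region")
  structure(list(P_select = best, HD_min = hd_min, hd_trace = trace,
                 n = as.integer(n), T = as.integer(T), seed = as.integer(seed),
                 spacing = spacing, n_degenerate = ndeg),
            class = "bkps_run")
}

#' @export
print.bkps_run <- function(x, ...) {
  cat(sprintf("bkps_run: n = %d, T = %d, HD_min = %.3f mm (%d degenerate draws)\n",
              x$n, x$T, x$HD_min, x$n_degenerate))
  invisible(x)
}

#' Rasterize selected key points into a supervision target
#'
#' Stamps a disk of the given radius at each key point; radius 0 marks the
#' single nearest pixel. The result is the binary target map the edge loss
#' compares against the BPP prediction.
#'
#' @param points m x 2 matrix of (x, y) key points (0-based, in bounds).
#' @param shape Integer (H, W).
#' @param radius Disk radius in pixels (default 1).
#' @return H x W 0/1 integer matrix.
#' @export
rasterize_keypoints <- function(points, shape, radius = 1) {
  points <- as.matrix(points)
  H <- shape[1]; W <- shape[2]
  if (nrow(points) > 0 &&
      (any(points[, 1] < 0 | points[, 1] > W - 1) ||
       any(points[, 2] < 0 | points[, 2] > H - 1)))
    stop("key points out of bounds")
  out <- matrix(0L, H, W)
  for (i in seq_len(nrow(points))) {
    px <- round(points[i, 1]); py <- round(points[i, 2])
    if (radius <= 0) {
      out[py + 1, px + 1] <- 1L
    } else {
      xs <- max(0, px - ceiling(radius)):min(W - 1, px + ceiling(radius))
      ys <- max(0, py - ceiling(radius)):min(H - 1, py + ceiling(radius))
      for (x in xs) for (y in ys)
        if ((x - points[i, 1])^2 + (y - points[i, 2])^2 <= radius^2 + 1e-9)
          out[y + 1, x + 1] <- 1L
    }
  }
  out
}
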