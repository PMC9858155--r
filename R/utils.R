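# Internal helpers shared across modules.
#
# Coordinate convention (package-wide): continuous image coordinates are
# 0-based with pixel centers at integers; x indexes columns, y indexes rows.
# R arrays remain 1-based internally, so array element [r, c] holds the pixel
# at (x, y) = (c - 1, r - 1).

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so generators never perturb user code.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

# 1-D Gaussian kernel truncated at floor(3*sigma) taps either side so blur
# support stays inside a 3*sigma Chebyshev neighbourhood (the locality the
# phantom generator promises).
gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, floor(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 2D matrix with reflect padding.
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_rows <- function(m) {
    n <- nrow(m)
    idx <- clamp(outer(seq_len(n), (-r):r, `+`), 1L, n)  # replicate edges
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

# Binary mask utilities ------------------------------------------------------

# Foreground pixels 4-adjacent to background (or the image border), returned
# as an n x 2 matrix of 0-based (x, y) coordinates.
mask_contour_points <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  edge <- core & !nb
  idx <- which(edge, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Tight bounding box of mask foreground in continuous 0-based coordinates
# (pixel-footprint extent, i.e. half a pixel beyond the outermost centers).
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask has no foreground pixels", call. = FALSE)
  c(x1 = min(idx[, 2]) - 1.5, y1 = min(idx[, 1]) - 1.5,
    x2 = max(idx[, 2]) - 0.5, y2 = max(idx[, 1]) - 0.5)
}

# Number of 4-connected foreground components (iterative flood fill).
n_components <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  ncomp <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo)) {
    ncomp <- ncomp + 1L
    stack <- todo[1]
    while (length(stack)) {
      p <- stack
      p <- p[m[p] & lab[p] == 0L]
      if (!length(p)) break
      lab[p] <- ncomp
      r <- ((p - 1L) %% H) + 1L
      cc <- ((p - 1L) %/% H) + 1L
      nbr <- c(p[r > 1L] - 1L, p[r < H] + 1L, p[cc > 1L] - H, p[cc < W] + H)
      stack <- unique(nbr[m[nbr] & lab[nbr] == 0L])
    }
    todo <- which(m & lab == 0L)
  }
  ncomp
}

# Cheap content fingerprint for cache keys (not cryptographic).
content_key <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (is.numeric(x) || is.logical(x)) {
      v <- as.numeric(x)
      paste(length(v),
            format(sum(v), digits = 17),
            format(sum(v * seq_along(v)), digits = 17), sep = ":")
    } else paste(as.character(x), collapse = ",")
  })
  paste(unlist(parts), collapse = "|")
}
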