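# Sub-pixel sampling: bilinear interpolation and RoI Align.
#
# Feature maps are H x W x C arrays (a plain matrix is treated as C = 1).
# Continuous coordinates are 0-based with pixel centers at integers; queries
# outside [0, W-1] x [0, H-1] are clamped to the edge (documented behavior,
# so alignment near borders is well defined rather than an error).

.as_fmap <- function(map) {
  if (is.matrix(map)) map <- array(map, dim = c(dim(map), 1L))
  stopifnot(length(dim(map)) == 3)
  map
}

#' Bilinear interpolation on a feature map
#'
#' The value at a continuous point (x, y) is the separable linear blend of
#' the four enclosing grid points: interpolate along x on the two rows
#' bracketing y, then blend those two partial results along y. The result is
#' exact at grid points.
#'
#' @param map H x W x C array (or H x W matrix, taken as one channel).
#' @param x,y Numeric vectors of equal length, continuous 0-based
#'   coordinates (x = column, y = row). Out-of-range values are clamped to
#'   the map edge.
#' @return length(x) x C matrix of interpolated values.
#' @export
bilinear_interpolate <- function(map, x, y) {
  map <- .as_fmap(map)
  H <- dim(map)[1]; W <- dim(map)[2]; C <- dim(map)[3]
  stopifnot(length(x) == length(y))
  x <- clamp(x, 0, W - 1); y <- clamp(y, 0, H - 1)
  x0 <- pmin(floor(x), max(W - 2, 0)); y0 <- pmin(floor(y), max(H - 2, 0))
  fx <- x - x0; fy <- y - y0
  if (W == 1) { x0 <- 0; fx <- 0 }
  if (H == 1) { y0 <- 0; fy <- 0 }
  r0 <- y0 + 1; c0 <- x0 + 1
  out <- matrix(0, length(x), C)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  HW <- H * W
  i00 <- r0 + H * (c0 - 1)
  i10 <- r0 + H * (pmin(c0, W - 1))          # c0 + 1 clamped
  i01 <- pmin(r0 + 1, H) + H * (c0 - 1)
  i11 <- pmin(r0 + 1, H) + H * (pmin(c0, W - 1))
  for (ch in seq_len(C)) {
    off <- (ch - 1) * HW
    out[, ch] <- w00 * map[i00 + off] + w10 * map[i10 + off] +
      w01 * map[i01 + off] + w11 * map[i11 + off]
  }
  out
}

# Sample positions and bilinear weights for an RoI Align call; shared by the
# functional op and the differentiable network layer (which needs the same
# gather indices for its scatter backward).
.roi_align_plan <- function(H, W, box, out_size, samples_per_bin, aligned = TRUE) {
  x1 <- box[1]; y1 <- box[2]; x2 <- box[3]; y2 <- box[4]
  if (!(x1 < x2 && y1 < y2)) stop("invalid box: need x1 < x2 and y1 < y2")
  if (x2 < 0 || y2 < 0 || x1 > W - 1 || y1 > H - 1)
    stop("box does not intersect the feature map extent")
  x1 <- clamp(x1, -0.5, W - 0.5); x2 <- clamp(x2, -0.5, W - 0.5)
  y1 <- clamp(y1, -0.5, H - 0.5); y2 <- clamp(y2, -0.5, H - 0.5)
  if (x2 - x1 <= 1e-9 || y2 - y1 <= 1e-9)
    stop(sprintf("degenerate (zero-area) box after clamping: [%g,%g]x[%g,%g]",
                 x1, x2, y1, y2))
  oh <- out_size[1]; ow <- out_size[2]
  s <- round(sqrt(samples_per_bin))
  if (s * s != samples_per_bin || s < 1)
    stop("samples_per_bin must be a positive perfect square (1, 4, 9, ...)")
  bw <- (x2 - x1) / ow; bh <- (y2 - y1) / oh
  frac <- (seq_len(s) - 0.5) / s
  # sample coordinates per output bin, regular s x s sub-grid inside the bin
  sx <- x1 + outer(rep(frac, times = 1), (seq_len(ow) - 1), function(f, j) (j + f) * bw)
  sy <- y1 + outer(rep(frac, times = 1), (seq_len(oh) - 1), function(f, i) (i + f) * bh)
  # full grid ordered (sub_row, bin_row, sub_col, bin_col), sub_row fastest,
  # matching the (s, oh, s, ow) reshape used when averaging bins
  gy <- rep(as.vector(sy), times = s * ow)
  gx <- rep(as.vector(sx), each = s * oh)
  if (!aligned) { gx <- round(gx); gy <- round(gy) }
  list(x = gx, y = gy, oh = oh, ow = ow, s = s)
}

#' RoI Align: pool a continuous box to a fixed small grid
#'
#' Divides the (continuous-coordinate) box into \code{out_size} bins, places
#' a regular sub-grid of bilinear sample points inside each bin, and
#' averages them. No coordinate is ever rounded, so sub-pixel spatial
#' location survives the pooling — the property that matters near fuzzy
#' lesion boundaries, where max pooling would discard weakly brighter key
#' pixels.
#'
#' @param map H x W x C array (or matrix).
#' @param box Numeric length-4 \code{c(x1, y1, x2, y2)} in continuous
#'   feature-map coordinates, \code{x1 < x2}, \code{y1 < y2}. Must intersect
#'   the map extent; a box degenerate after clamping is an error.
#' @param out_size Integer length-2 (h, w) of the pooled output (default
#'   c(7, 7)).
#' @param samples_per_bin Total bilinear samples per bin, a perfect square
#'   arranged as a centered sub-grid (default 4, i.e. 2 x 2).
#' @return out_size[1] x out_size[2] x C array.
#' @export
roi_align <- function(map, box, out_size = c(7L, 7L), samples_per_bin = 4L) {
  map <- .as_fmap(map)
  H <- dim(map)[1]; W <- dim(map)[2]; C <- dim(map)[3]
  pl <- .roi_align_plan(H, W, box, out_size, samples_per_bin)
  vals <- bilinear_interpolate(map, pl$x, pl$y)     # (oh*s * ow*s) x C
  oh <- pl$oh; ow <- pl$ow; s <- pl$s
  out <- array(0, dim = c(oh, ow, C))
  # rows of vals are ordered with y fastest: (sub_row within bin_row) fastest
  dim(vals) <- c(s, oh, s, ow, C)
  out[] <- apply(vals, c(2, 4, 5), mean)
  out
}
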