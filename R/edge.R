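# Edge attention: boundary points proposal (BPP) head and residual fusion.

#' Configuration of the boundary points proposal head
#'
#' The BPP head is a parallel multi-branch structure: one pure 1x1-reduction
#' branch plus one branch per dilation rate (1x1 reduction followed by a 3x3
#' convolution at that rate, padding = rate so spatial size is preserved).
#' Every convolution is followed by batch normalization (toggleable) and a
#' ReLU; branch outputs are concatenated, projected to one channel, and
#' sigmoid-activated into the edge-candidate map.
#'
#' @param dilation_rates Positive integers, one per dilated branch
#'   (default c(1, 2, 4), giving 4 branches total).
#' @param reduce_channels Width after the 1x1 reduction (default 64).
#' @param use_batchnorm Logical, default TRUE.
#' @return Object of class \code{bpp_config}.
#' @export
bpp_config <- function(dilation_rates = c(1L, 2L, 4L), reduce_channels = 64L,
                       use_batchnorm = TRUE) {
  if (any(dilation_rates < 1)) stop("dilation rates must be positive integers")
  structure(list(dilation_rates = as.integer(dilation_rates),
                 reduce_channels = as.integer(reduce_channels),
                 use_batchnorm = isTRUE(use_batchnorm),
                 n_branches = 1L + length(dilation_rates)),
            class = "bpp_config")
}

#' Initialize weights for the functional BPP forward
#'
#' @param C Input channel count.
#' @param config A \code{\link{bpp_config}}.
#' @param seed Seed for the random initialization.
#' @return Nested weight list consumed by \code{\link{bpp_forward}}.
#' @export
bpp_init <- function(C, config = bpp_config(), seed = 1L) {
  Cr <- config$reduce_channels
  with_local_seed(seed, {
    he <- function(k, cin, cout)
      array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
            dim = c(k, k, cin, cout))
    branches <- lapply(c(NA, config$dilation_rates), function(rate) {
      br <- list(W_red = he(1, C, Cr), b_red = rep(0, Cr),
                 g_red = rep(1, Cr), be_red = rep(0, Cr))
      if (!is.na(rate)) {
        br$rate <- as.integer(rate)
        br$W_dil <- he(3, Cr, Cr); br$b_dil <- rep(0, Cr)
        br$g_dil <- rep(1, Cr); br$be_dil <- rep(0, Cr)
      }
      br
    })
    list(branches = branches,
         W_out = he(1, config$n_branches * Cr, 1), b_out = 0)
  })
}

# Batch-statistics normalization over the spatial extent, per channel.
.bn_fn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  M <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(M); v <- colMeans(M^2) - mu^2
  M <- sweep(sweep(M, 2, mu, `-`), 2, sqrt(v + eps), `/`)
  M <- sweep(sweep(M, 2, gamma, `*`), 2, beta, `+`)
  array(M, dim = d)
}

#' Boundary points proposal forward pass (functional)
#'
#' Produces the edge-candidate map F_points in (0, 1): per branch a 1x1
#' channel reduction, then (for dilated branches) a 3x3 convolution at the
#' branch's dilation rate, batch normalization and ReLU; branch outputs are
#' concatenated, projected to 1 channel, and passed through a sigmoid.
#' Spatial size is preserved (padding = dilation).
#'
#' @param Z H x W x C feature map (the mixed-attention output).
#' @param weights From \code{\link{bpp_init}} (or compatible).
#' @param config The \code{\link{bpp_config}} used to build \code{weights}.
#' @return H x W x 1 edge map with entries strictly in (0, 1).
#' @export
bpp_forward <- function(Z, weights, config = bpp_config()) {
  Z <- .as_fmap(Z)
  stopifnot_finite(Z, "bpp_forward input")
  if (max(config$dilation_rates) >= min(dim(Z)[1], dim(Z)[2]))
    stop("dilation too large for the input spatial extent")
  outs <- lapply(weights$branches, function(br) {
    h <- conv2d_fn(Z, br$W_red, br$b_red, pad = 0L)
    if (config$use_batchnorm) h <- .bn_fn(h, br$g_red, br$be_red)
    h <- h * (h > 0)
    if (!is.null(br$W_dil)) {
      h <- conv2d_fn(h, br$W_dil, br$b_dil, dilation = br$rate)
      if (config$use_batchnorm) h <- .bn_fn(h, br$g_dil, br$be_dil)
      h <- h * (h > 0)
    }
    h
  })
  cat_ <- array(unlist(outs), dim = c(dim(Z)[1], dim(Z)[2],
                                      config$n_branches * config$reduce_channels))
  logits <- conv2d_fn(cat_, weights$W_out, weights$b_out, pad = 0L)
  1 / (1 + exp(-logits))
}

#' Residual edge-attention fusion
#'
#' Re-weights tumor features by the edge-candidate map through a skip
#' connection: \eqn{F_{edge} = F_{tumor} \otimes (1 \oplus F_{points})},
#' i.e. \code{F_tumor + F_tumor * F_points} with the single-channel edge map
#' broadcast across channels. When the attention response is near zero the
#' fusion leaves the original features (approximately) unchanged, so the
#' module can only enhance fuzzy-boundary features, never erase them.
#'
#' @param F_tumor H x W x C feature map.
#' @param F_points H x W x 1 edge map (values in (0, 1)).
#' @return H x W x C fused feature map.
#' @export
edge_fuse <- function(F_tumor, F_points) {
  F_tumor <- .as_fmap(F_tumor); F_points <- .as_fmap(F_points)
  if (!all(dim(F_tumor)[1:2] == dim(F_points)[1:2]))
    stop("spatial dimensions of F_tumor and F_points must match")
  if (dim(F_points)[3] != 1) stop("F_points must have a single channel")
  F_tumor * (1 + as.vector(F_points))
}
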