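# Mixed attention: parallel channel-wise and position-wise self-attention.
#
# Both branches are residual: a freshly initialized module (learning factors
# omega = phi = 0) passes features through unchanged, so attention can only
# enhance, never replace, the head-mask features.

.row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

.fmap_to_mat <- function(Of) {
  Of <- .as_fmap(Of)
  d <- dim(Of)
  list(M = matrix(Of, d[1] * d[2], d[3]), d = d)
}

#' Channel self-attention with residual fusion
#'
#' Computes channel-to-channel attention weights
#' \eqn{a_{jk} = \mathrm{softmax}_k(Of_k \cdot Of_j)} from dot products of
#' the flattened channel features, soft-weights the channels, and adds the
#' result back residually: \eqn{B_j = \omega \sum_k a_{jk} Of_k + Of_j}.
#'
#' @param Of H x W x C feature map.
#' @param omega Scalar learning factor (0 gives the identity).
#' @param return_weights If TRUE also return the C x C row-stochastic
#'   attention matrix.
#' @return Feature map of the same shape (or list with \code{out} and
#'   \code{A} when \code{return_weights}).
#' @export
channel_attention <- function(Of, omega = 0, return_weights = FALSE) {
  fm <- .fmap_to_mat(Of)
  stopifnot_finite(fm$M, "channel_attention input")
  G <- crossprod(fm$M)            # G[j, k] = Of_j . Of_k
  A <- .row_softmax(G)
  B <- omega * (fm$M %*% t(A)) + fm$M
  out <- array(B, dim = fm$d)
  if (return_weights) list(out = out, A = A) else out
}

#' Parameters for the spatial attention branch
#'
#' The branch reduces channels to floor(C/8) with three learned 1x1
#' projections (queries Q, keys S, values V), and restores C channels with a
#' fourth 1x1 projection after the position-weighted sum.
#'
#' @param C Input channel count; floor(C/8) must be >= 1.
#' @param seed Seed for the random initialization.
#' @return List of projection matrices/biases \code{Wq, Ws, Wv, bq, bs, bv,
#'   Wo, bo} and the reduced width \code{Cr}.
#' @export
spatial_attention_params <- function(C, seed = 1L) {
  Cr <- floor(C / 8)
  if (Cr < 1) stop("floor(C/8) must be >= 1 for the spatial attention branch")
  with_local_seed(seed, {
    rnd <- function(n, m) matrix(stats::rnorm(n * m, 0, sqrt(2 / n)), n, m)
    list(Wq = rnd(C, Cr), Ws = rnd(C, Cr), Wv = rnd(C, Cr),
         bq = rep(0, Cr), bs = rep(0, Cr), bv = rep(0, Cr),
         Wo = rnd(Cr, C), bo = rep(0, C), Cr = Cr)
  })
}

#' Position (spatial) self-attention with residual fusion
#'
#' Projects the N = H*W flattened features to reduced width with 1x1
#' projections Q, S, V; forms position-to-position weights
#' \eqn{e_{jk} = \mathrm{softmax}_k(Q_k \cdot S_j)}; soft-weights V; projects
#' back to C channels with a 1x1 projection; and fuses residually:
#' \eqn{U_j = \varphi \sum_k e_{jk} V_k + Of_j} (the back-projection applied
#' to the weighted sum).
#'
#' @param Of H x W x C feature map. H*W is materialized as an N x N grid,
#'   so the op is meant for small head maps (N <= 4096).
#' @param params From \code{\link{spatial_attention_params}}.
#' @param phi Scalar learning factor (0 gives the identity).
#' @param return_weights If TRUE also return the N x N row-stochastic grid.
#' @return Feature map of the same shape (or list \code{out}, \code{E}).
#' @export
spatial_attention <- function(Of, params, phi = 0, return_weights = FALSE) {
  fm <- .fmap_to_mat(Of)
  stopifnot_finite(fm$M, "spatial_attention input")
  N <- nrow(fm$M)
  if (N > 4096) stop("spatial attention grid would exceed 4096 positions")
  M <- fm$M
  Q <- sweep(M %*% params$Wq, 2, params$bq, `+`)
  S <- sweep(M %*% params$Ws, 2, params$bs, `+`)
  V <- sweep(M %*% params$Wv, 2, params$bv, `+`)
  E <- .row_softmax(S %*% t(Q))   # E[j, k] = softmax_k(Q_k . S_j)
  P <- sweep((E %*% V) %*% params$Wo, 2, params$bo, `+`)
  U <- phi * P + M
  out <- array(U, dim = fm$d)
  if (return_weights) list(out = out, E = E) else out
}

#' Mixed attention: parallel or serial channel + spatial branches
#'
#' In the parallel mode both branches read the same input and their outputs
#' are summed, Z = B + U (each branch carries its own residual copy of the
#' input). The serial modes feed one branch's output into the other — the
#' wiring used by the attention-order ablation.
#'
#' @param Of H x W x C feature map.
#' @param mode One of "parallel", "channel_then_spatial",
#'   "spatial_then_channel".
#' @param omega,phi Learning factors for the channel / spatial branch.
#' @param params Spatial branch parameters; defaults to
#'   \code{spatial_attention_params(C)}.
#' @return Feature map of the same shape.
#' @export
mixed_attention <- function(Of, mode = c("parallel", "channel_then_spatial",
                                         "spatial_then_channel"),
                            omega = 0, phi = 0, params = NULL) {
  mode <- match.arg(mode)
  Of <- .as_fmap(Of)
  if (is.null(params)) params <- spatial_attention_params(dim(Of)[3])
  switch(mode,
    parallel = channel_attention(Of, omega) + spatial_attention(Of, params, phi),
    channel_then_spatial = spatial_attention(channel_attention(Of, omega), params, phi),
    spatial_then_channel = channel_attention(spatial_attention(Of, params, phi), omega))
}
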