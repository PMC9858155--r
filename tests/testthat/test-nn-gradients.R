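# Every hand-derived backward pass is validated against central-difference
# numerical gradients on small random inputs.

test_that("convolution, batch norm and linear layers backpropagate exactly", {
  set.seed(4)
  x <- array(rnorm(6 * 7 * 3), c(6, 7, 3))
  expect_layer_gradients(edgeseg:::nn_conv2d(3, 4, k = 3), x)
  expect_layer_gradients(edgeseg:::nn_conv2d(3, 2, k = 3, dilation = 2), x)
  expect_layer_gradients(edgeseg:::nn_conv2d(3, 2, k = 3, stride = 2), x)
  expect_layer_gradients(edgeseg:::nn_bn(3), x)
  expect_layer_gradients(edgeseg:::nn_linear(21, 5), matrix(rnorm(42), 2, 21))
})

test_that("attention and BPP layers backpropagate exactly", {
  set.seed(5)
  x8 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  ca <- edgeseg:::nn_channel_attn(); ca$omega$val <- 0.8
  expect_layer_gradients(ca, x8)
  sa <- edgeseg:::nn_spatial_attn(8, seed = 2); sa$phi$val <- 0.6
  expect_layer_gradients(sa, x8)
  ma <- edgeseg:::nn_mixed_attn(8, "parallel", seed = 3)
  ma$ca$omega$val <- 0.5; ma$sa$phi$val <- 0.4
  expect_layer_gradients(ma, x8)
  ms <- edgeseg:::nn_mixed_attn(8, "channel_then_spatial", seed = 3)
  ms$ca$omega$val <- 0.3; ms$sa$phi$val <- 0.7
  expect_layer_gradients(ms, x8)
  bpp <- edgeseg:::nn_bpp(8, bpp_config(dilation_rates = c(1, 2),
                                        reduce_channels = 4))
  expect_layer_gradients(bpp, array(rnorm(8 * 8 * 8), c(8, 8, 8)), tol = 1e-5)
})

test_that("RoI Align, upsample, residual block and maxpool backpropagate exactly", {
  set.seed(6)
  x <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  roi <- edgeseg:::nn_roi_align(c(3, 3), 4)
  expect_layer_gradients(roi, x,
                         fwd = function(l, xx) l$fwd(xx, c(1.3, 2.1, 7.9, 8.4), TRUE))
  expect_layer_gradients(edgeseg:::nn_upsample(13, 11), x)
  expect_layer_gradients(edgeseg:::nn_resblock(2, 4, stride = 2), x, tol = 1e-5)
  xm <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  # break pooling ties so the argmax subgradient is well defined
  xm <- xm + array(seq_along(xm) * 1e-3, dim = dim(xm))
  expect_layer_gradients(edgeseg:::nn_maxpool2(), xm)
})

test_that("edge fusion layer routes gradients to both inputs", {
  set.seed(7)
  ft <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  fp <- array(runif(9, 0.2, 0.8), c(3, 3, 1))
  fuse <- edgeseg:::nn_edge_fuse()
  y <- fuse$fwd(ft, fp, TRUE)
  dy <- array(rnorm(length(y)), dim = dim(y))
  d <- fuse$bwd(dy)
  gt_ft <- num_grad(function(a) sum(fuse$fwd(a, fp, TRUE) * dy), ft)
  gt_fp <- num_grad(function(a) sum(fuse$fwd(ft, a, TRUE) * dy), fp)
  expect_lt(max(abs(d$d_tumor - gt_ft)), 1e-8)
  expect_lt(max(abs(d$d_points - gt_fp)), 1e-8)
})

test_that("optimizers update parameters and snapshots restore them bitwise", {
  set.seed(8)
  ly <- edgeseg:::nn_linear(4, 2)
  x <- matrix(rnorm(12), 3, 4)
  tgt <- matrix(rnorm(6), 3, 2)
  opt <- edgeseg:::make_optimizer(ly$params, kind = "adamw", lr = 0.05)
  loss0 <- sum((ly$fwd(x, TRUE) - tgt)^2)
  for (i in 1:30) {
    y <- ly$fwd(x, TRUE)
    ly$bwd(2 * (y - tgt))
    opt$step()
  }
  expect_lt(sum((ly$fwd(x, TRUE) - tgt)^2), loss0 / 4)
  snap <- edgeseg:::params_snapshot(ly$params)
  w_saved <- ly$params[[1]]$val
  y <- ly$fwd(x, TRUE); ly$bwd(2 * (y - tgt)); opt$step()
  expect_false(identical(ly$params[[1]]$val, w_saved))
  edgeseg:::params_restore(ly$params, snap)
  expect_identical(ly$params[[1]]$val, w_saved)
})
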