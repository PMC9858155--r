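test_that("configured shapes reproduce the reference layer table at 512 input", {
  shp <- ean_shapes(ean_config())
  expect_equal(shp[shp$layer == "P2", c("height", "width", "channels")],
               data.frame(height = 128, width = 128, channels = 256),
               ignore_attr = TRUE)
  expect_equal(shp[shp$layer == "P6", c("height", "width", "channels")],
               data.frame(height = 8, width = 8, channels = 256),
               ignore_attr = TRUE)
  expect_equal(shp$height[shp$layer %in% paste0("C", 1:5)],
               c(256, 128, 64, 32, 16))
  expect_equal(shp$channels[shp$layer %in% paste0("C", 2:5)],
               c(256, 512, 1024, 2048))
  expect_error(ean_config(input_size = 100), "divisible")
})

test_that("tiny network builds and a forward pass honors the shape contract", {
  net <- build_ean(ean_config(tiny = TRUE, seed = 3))
  s <- generate_phantom(tiny_phantom_config(seed = 11))
  out <- ean_forward(net, s$image)
  expect_identical(dim(out$mask), c(64L, 64L))
  expect_identical(dim(out$boundary_map), c(64L, 64L))
  expect_true(all(out$mask >= 0 & out$mask <= 1))
  expect_true(all(out$boundary_map >= 0 & out$boundary_map <= 1))
  expect_true(all(is.finite(unlist(out$boxes))))
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-12)
  # determinism in evaluation mode
  out2 <- ean_forward(net, s$image)
  expect_identical(out$mask, out2$mask)
  expect_identical(out$boundary_map, out2$boundary_map)
  # all-zero image still yields finite probabilities
  oz <- ean_forward(net, matrix(0, 64, 64))
  expect_true(all(is.finite(oz$mask)))
  expect_error(ean_forward(net, matrix(0, 32, 32)), "input size")
})

test_that("flag combinations are validated against the component-study rows", {
  expect_error(ean_config(tiny = TRUE,
                           flags = list(CA = FALSE, SA = FALSE, EA = TRUE)),
               "EA requires")
  expect_error(ean_config(tiny = TRUE, flags = list(EA = FALSE, ES = TRUE)),
               "ES")
  expect_error(ean_config(tiny = TRUE, flags = list(RS = TRUE, ES = FALSE)),
               "RS")
})

test_that("ablation flags shrink the trainable graph monotonically", {
  census <- function(fl) ean_module_census(build_ean(
    ean_config(tiny = TRUE, seed = 1, flags = fl)))
  full <- census(list())
  no_rs <- census(list(RS = FALSE))
  no_es <- census(list(RS = FALSE, ES = FALSE))
  no_ea <- census(list(RS = FALSE, ES = FALSE, EA = FALSE))
  plain <- census(list(RS = FALSE, ES = FALSE, EA = FALSE, CA = FALSE,
                       SA = FALSE))
  expect_lt(no_rs$n_params, full$n_params)
  expect_lt(no_ea$n_params, no_es$n_params)
  expect_lt(plain$n_params, no_ea$n_params)
  expect_false(plain$has_bpp)
  expect_false(plain$has_channel_attention)
  expect_false(plain$has_spatial_attention)
  expect_false(plain$has_region_head)
  # plain topology still runs end to end, without a boundary output
  s <- generate_phantom(tiny_phantom_config(seed = 2))
  net <- build_ean(ean_config(tiny = TRUE, seed = 1,
                                   flags = list(RS = FALSE, ES = FALSE,
                                                EA = FALSE, CA = FALSE,
                                                SA = FALSE)))
  o <- ean_forward(net, s$image)
  expect_null(o$boundary_map)
  expect_identical(dim(o$mask), c(64L, 64L))
})

test_that("the network boundary head composes from the standalone attention ops", {
  net <- build_ean(ean_config(tiny = TRUE, seed = 9))
  s <- generate_phantom(tiny_phantom_config(seed = 4))
  o <- ean_forward(net, s$image, return_features = TRUE)
  Z_standalone <- net$ma$fwd(o$Of, train = FALSE)
  expect_equal(Z_standalone, o$Z, tolerance = 1e-12)
  Fp_standalone <- net$bpp$fwd(Z_standalone, train = FALSE)
  expect_equal(Fp_standalone, o$F_points, tolerance = 1e-12)
  pasted <- edgeseg:::.paste_patch(Fp_standalone[, , 1], o$roi, 64)
  expect_equal(pasted, o$boundary_map, tolerance = 1e-12)
})

test_that("edge and region supervision reach the BPP and fusion-side parameters", {
  net <- build_ean(ean_config(tiny = TRUE, seed = 4))
  s <- generate_phantom(tiny_phantom_config(seed = 6))
  kp <- select_boundary_keypoints(s$image, s$mask, n = 20, T = 10,
                                  seed = 1)$P_select
  set.seed(1)
  edgeseg:::.zero_grads(net$params)
  edgeseg:::.train_step(net, s$image, s$mask, kp,
                        loss_weights = c(cls = 0, box = 0, mask = 0,
                                         edge = 1, reg = 0))
  g_bpp <- sum(vapply(net$bpp$params, function(p) sum(abs(p$grad)), 0))
  expect_gt(g_bpp, 0)
  edgeseg:::.zero_grads(net$params)
  edgeseg:::.train_step(net, s$image, s$mask, kp,
                        loss_weights = c(cls = 0, box = 0, mask = 0,
                                         edge = 0, reg = 1))
  expect_gt(sum(abs(net$reg_conv$W$grad)), 0)
  g_attn <- sum(vapply(net$ma$params, function(p) sum(abs(p$grad)), 0))
  expect_gt(g_attn, 0)
})

test_that("quantized pooling (alignment off) differs from aligned sampling", {
  set.seed(10)
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  box <- c(1.37, 2.21, 9.83, 10.46)
  aligned <- edgeseg:::nn_roi_align(c(7, 7), 4, aligned = TRUE)
  rounded <- edgeseg:::nn_roi_align(c(7, 7), 4, aligned = FALSE)
  expect_gt(max(abs(aligned$fwd(x, box, FALSE) - rounded$fwd(x, box, FALSE))), 0)
})
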