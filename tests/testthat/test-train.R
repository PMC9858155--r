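test_that("augmentation with neutral settings is the identity; flips are involutions", {
  s <- generate_phantom(tiny_phantom_config(seed = 13))
  id <- augment_sample(s, seed = 1, scale = c(1, 1), angle = c(0, 0),
                       shift = 0, shear = 0, flip = FALSE, salt = 0)
  expect_equal(id$image, s$image, tolerance = 1e-12)
  expect_identical(unname(id$mask), unname(s$mask))
  # a horizontal flip is exact on the pixel grid and an involution
  flip_once <- function(x) {
    out <- x
    out$image <- x$image[, ncol(x$image):1]
    out$mask <- x$mask[, ncol(x$mask):1]
    out
  }
  expect_identical(flip_once(flip_once(s))$image, s$image)
})

test_that("90-degree rotation conserves mask area exactly", {
  s <- generate_phantom(tiny_phantom_config(seed = 14))
  rot <- augment_sample(s, seed = 2, scale = c(1, 1), angle = c(90, 90),
                        shift = 0, shear = 0, flip = FALSE, salt = 0)
  expect_equal(sum(rot$mask), sum(s$mask))
  expect_equal(rot$meta$area, s$meta$area)
})

test_that("geometry is applied identically to image and mask", {
  s <- generate_phantom(crisp_phantom_config(seed = 15))
  a <- augment_sample(s, seed = 3, salt = 0)
  thr <- (0.15 + 0.85) / 2
  inside <- a$mask == 1L
  # interior of the transported mask stays bright, far background stays dark
  expect_gt(mean(a$image[inside]), 0.7)
  expect_lt(mean(a$image[!inside]), 0.3)
  M <- attr(a, "affine")
  expect_identical(dim(M), c(2L, 3L))
  ct <- edgeseg:::mask_contour_points(s$mask)
  moved <- edgeseg:::.transform_points(ct, M)
  keep <- moved[, 1] >= 0 & moved[, 1] <= 63 & moved[, 2] >= 0 & moved[, 2] <= 63
  d2 <- edgeseg:::.min_dist2(moved[keep, , drop = FALSE],
                             edgeseg:::mask_contour_points(a$mask))
  expect_lt(sqrt(stats::median(d2)), 1.5)  # transported contour tracks the new contour
})

test_that("fixed-seed training is bitwise reproducible and zero LR freezes the trace", {
  dat <- make_phantom_set(8, base_seed = 31)
  ncfg <- ean_config(tiny = TRUE, seed = 2)
  tcfg <- train_config(tiny_mode = TRUE, epochs = 2, seed = 5)
  f1 <- ean_train(dat, net_config = ncfg, config = tcfg, verbose = FALSE)
  f2 <- ean_train(dat, net_config = ncfg, config = tcfg, verbose = FALSE)
  expect_identical(f1$history$l_total, f2$history$l_total)
  f0 <- ean_train(dat, net_config = ncfg,
                   config = train_config(tiny_mode = TRUE, epochs = 3, seed = 5,
                                         learning_rate = 0, augment = FALSE),
                   verbose = FALSE)
  expect_lt(diff(range(f0$history$l_total)), 1e-10)
})

test_that("checkpointing resumes with the uninterrupted run's next-epoch loss", {
  dat <- make_phantom_set(8, base_seed = 41)
  ncfg <- ean_config(tiny = TRUE, seed = 3)
  dir <- withr::local_tempdir()
  full <- ean_train(dat, net_config = ncfg,
                     config = train_config(tiny_mode = TRUE, epochs = 3, seed = 9),
                     checkpoint_dir = dir, verbose = FALSE)
  resumed <- ean_train(dat, net_config = ncfg,
                        config = train_config(tiny_mode = TRUE, epochs = 3, seed = 9),
                        resume = file.path(dir, "epoch_002.rds"), verbose = FALSE)
  expect_lt(abs(full$history$l_total[3] -
                  resumed$history$l_total[nrow(resumed$history)]), 1e-6)
})

test_that("key-point target cache is content-addressed", {
  s <- generate_phantom(tiny_phantom_config(seed = 17))
  cache <- new.env(); cache$store <- new.env(parent = emptyenv())
  cache$hits <- 0L; cache$misses <- 0L
  k1 <- edgeseg:::.bkps_target(cache, s$image, s$mask, 10L, 5L, 1L)
  k2 <- edgeseg:::.bkps_target(cache, s$image, s$mask, 10L, 5L, 1L)
  expect_identical(k1, k2)
  expect_equal(cache$hits, 1L)
  expect_equal(cache$misses, 1L)
  edgeseg:::.bkps_target(cache, s$image, s$mask, 12L, 5L, 1L)  # changed params
  expect_equal(cache$misses, 2L)
  s2 <- generate_phantom(tiny_phantom_config(seed = 18))     # changed content
  edgeseg:::.bkps_target(cache, s2$image, s2$mask, 10L, 5L, 1L)
  expect_equal(cache$misses, 3L)
})

test_that("short training decreases the smoothed loss and the model methods work", {
  dat <- make_phantom_set(14, base_seed = 51)
  fit <- ean_train(dat[1:12], val_samples = dat[13:14],
                    net_config = ean_config(tiny = TRUE, seed = 1),
                    config = train_config(tiny_mode = TRUE, epochs = 4, seed = 1),
                    verbose = FALSE)
  h <- fit$history
  expect_lt(h$l_total[4], h$l_total[1])
  expect_s3_class(fit, "ean_model")
  expect_output(print(fit), "edge-attention segmentation model")
  pm <- predict(fit, dat[[13]])
  expect_true(all(pm %in% c(0L, 1L)))
  pp <- predict(fit, dat[[13]], type = "prob")
  expect_true(all(pp >= 0 & pp <= 1))
  ev <- ean_evaluate(fit, dat[13:14])
  expect_equal(nrow(ev$per_image), 2)
  expect_true(is.finite(ev$mean["DSC"]))
})
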