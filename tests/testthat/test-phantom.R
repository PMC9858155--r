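test_that("phantom generation is deterministic and respects the mask contract", {
  cfg <- tiny_phantom_config(seed = 7)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_identical(dim(s1$image), dim(s1$mask))
  expect_gt(s1$meta$area, 0)
  expect_equal(edgeseg:::n_components(s1$mask), 1)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("without blur or noise the half-contrast level set equals the mask", {
  s <- generate_phantom(crisp_phantom_config(seed = 3))
  thr <- (0.15 + 0.85) / 2
  expect_identical(unname((s$image >= thr) * 1L), unname(s$mask * 1L))
})

test_that("mean lesion area over many draws stays inside the radius-implied bounds", {
  areas <- vapply(1:300, function(i) {
    generate_phantom(phantom_config(image_size = 64L,
                                    lesion_radius_range = c(10, 20),
                                    boundary_blur_sigma = 0, n_distractors = 0L,
                                    noise_sigma = 0, salt_fraction = 0,
                                    seed = i))$meta$area
  }, 0)
  expect_gt(mean(areas), pi * 10^2)
  expect_lt(mean(areas), pi * 20^2)
})

test_that("rim blur is local: pixels beyond 3 sigma of the boundary are untouched", {
  sig <- 1.5
  cfg_blur <- tiny_phantom_config(seed = 5, blur = sig, noise = 0, salt = 0,
                                  distractors = 2L)
  cfg_sharp <- tiny_phantom_config(seed = 5, blur = 0, noise = 0, salt = 0,
                                   distractors = 2L)
  sb <- generate_phantom(cfg_blur)
  ss <- generate_phantom(cfg_sharp)
  expect_identical(sb$mask, ss$mask)
  ct <- edgeseg:::mask_contour_points(ss$mask)
  n <- nrow(ss$image)
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  cheb <- matrix(Inf, n, n)
  for (k in seq_len(nrow(ct)))
    cheb <- pmin(cheb, pmax(abs(xs - ct[k, 1]), abs(ys - ct[k, 2])))
  far <- cheb > 3 * sig
  expect_gt(sum(far), 0)
  expect_equal(sb$image[far], ss$image[far], tolerance = 1e-12)
})

test_that("infeasible lesion sizes are rejected", {
  expect_error(phantom_config(image_size = 64, lesion_radius_range = c(10, 40)),
               "image_size / 2")
  cfg <- phantom_config(image_size = 64, lesion_radius_range = c(28, 31.5))
  expect_error(generate_phantom(cfg), "margin")
})

test_that("dataset writing round-trips masks exactly and counts files", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config(seed = 21)
  man <- write_phantom_dataset(5, dir, cfg)
  expect_length(list.files(dir, pattern = "^image_.*png$"), 5)
  expect_length(list.files(dir, pattern = "^mask_.*png$"), 5)
  back <- read_phantom_dataset(man)
  expect_length(back, 5)
  cfg1 <- cfg
  orig <- generate_phantom(cfg1)
  expect_identical(unname(back[[1]]$mask), unname(orig$mask))
  expect_lt(max(abs(back[[1]]$image - orig$image)), 1 / 255)
  expect_error(write_phantom_dataset(2, dir, cfg), "force")
  # empty dataset: manifest only
  dir2 <- withr::local_tempdir()
  man2 <- write_phantom_dataset(0, dir2, cfg)
  expect_length(jsonlite::read_json(man2)$pairs, 0)
  expect_length(list.files(dir2, pattern = "png$"), 0)
})
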