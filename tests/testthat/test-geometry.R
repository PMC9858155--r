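test_that("bilinear interpolation is exact at grid points and symmetric at cell centers", {
  set.seed(1)
  m <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_equal(bilinear_interpolate(m, 3, 5)[1, ], m[6, 4, ], tolerance = 1e-14)
  corners <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(bilinear_interpolate(corners, 0.5, 0.5)[1, 1], 0.5)
})

test_that("bilinear interpolation matches the separable 1-D oracle", {
  set.seed(2)
  m <- matrix(rnorm(64), 8, 8)
  xq <- runif(100, 0, 7); yq <- runif(100, 0, 7)
  got <- bilinear_interpolate(m, xq, yq)[, 1]
  oracle <- vapply(seq_along(xq), function(i) {
    x <- xq[i]; y <- yq[i]
    x0 <- min(floor(x), 6); y0 <- min(floor(y), 6)
    # interpolate along x on the two bracketing rows, then along y
    r1 <- m[y0 + 1, x0 + 1] * (x0 + 1 - x) + m[y0 + 1, x0 + 2] * (x - x0)
    r2 <- m[y0 + 2, x0 + 1] * (x0 + 1 - x) + m[y0 + 2, x0 + 2] * (x - x0)
    r1 * (y0 + 1 - y) + r2 * (y - y0)
  }, 0)
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("out-of-range queries clamp to the edge", {
  m <- matrix(1:12, 3, 4)
  expect_equal(bilinear_interpolate(m, -5, -5)[1, 1], m[1, 1])
  expect_equal(bilinear_interpolate(m, 99, 99)[1, 1], m[3, 4])
})

test_that("roi_align preserves constants and recovers integer-aligned patches", {
  cm <- array(3.7, c(10, 10, 2))
  expect_lt(max(abs(roi_align(cm, c(1.2, 2.3, 8.1, 7.7)) - 3.7)), 1e-12)
  set.seed(3)
  mp <- array(rnorm(144), c(12, 12, 1))
  # box covering the pixel footprint of rows 3..9, cols 4..10 (0-based x 3..9)
  out <- roi_align(mp, c(2.5, 1.5, 9.5, 8.5), c(7, 7), samples_per_bin = 1)
  expect_equal(out[, , 1], mp[3:9, 4:10, 1], tolerance = 1e-12)
})

test_that("roi_align agrees with a dense-oversampling oracle", {
  # smooth positive field: the regime where the refinement limit is tight
  # and per-bin relative error is well defined
  xs <- matrix(rep(0:9, each = 10), 10, 10)
  ys <- matrix(rep(0:9, times = 10), 10, 10)
  mp <- array(c(1.5 + 0.5 * sin(xs / 3) * cos(ys / 4),
                2 - 0.3 * cos(xs / 2.5) * sin(ys / 3.5)), c(10, 10, 2))
  box <- c(1.7, 0.9, 8.3, 8.8)
  got <- roi_align(mp, box, c(5, 5), samples_per_bin = 4)
  dense <- roi_align(mp, box, c(5, 5), samples_per_bin = 100)  # 10x10 sub-grid
  expect_lt(max(abs(got - dense) / abs(dense)), 0.02)
})

test_that("roi_align converges monotonically under sample refinement", {
  set.seed(5)
  mp <- array(rnorm(100), c(10, 10, 1))
  box <- c(0.3, 1.1, 8.9, 9.2)
  dense <- roi_align(mp, box, c(4, 4), samples_per_bin = 144)
  errs <- vapply(c(1, 4, 16, 64), function(s)
    max(abs(roi_align(mp, box, c(4, 4), samples_per_bin = s) - dense)), 0)
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("roi_align is equivariant to whole-pixel shifts", {
  set.seed(6)
  base <- array(rnorm(196), c(14, 14, 1))
  shifted <- array(0, c(14, 14, 1))
  shifted[2:14, 2:14, ] <- base[1:13, 1:13, ]
  box <- c(2.2, 3.1, 9.7, 10.4)
  a <- roi_align(base, box, c(3, 3))
  b <- roi_align(shifted, box + c(1, 1, 1, 1), c(3, 3))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("averaging, not max: a constructed map distinguishes the two", {
  # one bright pixel inside the bin: average must be far below the max
  mp <- array(0, c(8, 8, 1)); mp[4, 4, 1] <- 8
  out <- roi_align(mp, c(1.5, 1.5, 5.5, 5.5), c(1, 1), samples_per_bin = 16)
  expect_lt(out[1, 1, 1], 8)
  expect_gt(out[1, 1, 1], 0)
})

test_that("degenerate and non-intersecting boxes are rejected", {
  mp <- array(0, c(8, 8, 1))
  expect_error(roi_align(mp, c(5, 5, 5, 5)), "x1 < x2")
  expect_error(roi_align(mp, c(20, 20, 30, 30)), "intersect")
})
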