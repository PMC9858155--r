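# Shared fixtures and oracles, all generated in code.

tiny_phantom_config <- function(seed = 1L, blur = 1.5, noise = 0.02,
                                salt = 0.002, distractors = 3L) {
  phantom_config(image_size = 64L, lesion_radius_range = c(10, 18),
                 boundary_blur_sigma = blur, n_distractors = distractors,
                 noise_sigma = noise, salt_fraction = salt, seed = seed)
}

crisp_phantom_config <- function(seed = 1L) {
  tiny_phantom_config(seed = seed, blur = 0, noise = 0, salt = 0,
                      distractors = 0L)
}

# Exact disk mask (radius r, centered) used by the key-point search checks.
disk_mask <- function(n = 128L, r = 30, cx = (n - 1) / 2, cy = (n - 1) / 2) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  m <- ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1L
  storage.mode(m) <- "integer"
  m
}

# Central-difference numerical gradient of scalar f at array x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Compare a layer's analytic input/parameter gradients to numerical ones.
expect_layer_gradients <- function(ly, x, tol = 1e-6,
                                   fwd = function(l, xx) l$fwd(xx, TRUE)) {
  y <- fwd(ly, x)
  set.seed(42)
  dy <- array(rnorm(length(y)), dim = dim(y))
  edgeseg:::.zero_grads(ly$params)
  y <- fwd(ly, x)
  dx <- ly$bwd(dy)
  gx <- num_grad(function(xx) sum(fwd(ly, xx) * dy), x)
  expect_lt(max(abs(dx - gx)) / max(1, max(abs(gx))), tol)
  for (p in ly$params) {
    v0 <- p$val
    gp <- num_grad(function(vv) { p$val <- vv; r <- sum(fwd(ly, x) * dy); p$val <- v0; r },
                   as.array(v0))
    expect_lt(max(abs(as.array(p$grad) - gp)) / max(1, max(abs(gp))), tol)
  }
  invisible(NULL)
}
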