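test_that("channel attention matches the explicit summation oracle and is identity at omega 0", {
  set.seed(2)
  Of <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_identical(channel_attention(Of, omega = 0), Of)
  res <- channel_attention(Of, omega = 1, return_weights = TRUE)
  M <- matrix(Of, 16, 3)
  G <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3) G[j, k] <- sum(M[, k] * M[, j])
  A <- t(apply(G, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  B <- matrix(0, 16, 3)
  for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + A[j, k] * M[, k]
    B[, j] <- acc + M[, j]
  }
  expect_lt(max(abs(res$out - array(B, c(4, 4, 3)))), 1e-6)
  expect_equal(unname(rowSums(res$A)), rep(1, 3), tolerance = 1e-12)
})

test_that("identical channels give uniform attention weights 1/C", {
  base <- matrix(rnorm(16), 4, 4)
  Of <- array(rep(base, 3), c(4, 4, 3))
  A <- channel_attention(Of, omega = 0.5, return_weights = TRUE)$A
  expect_equal(unname(A), matrix(1 / 3, 3, 3), tolerance = 1e-12)
})

test_that("channel attention is equivariant to channel permutation", {
  set.seed(8)
  Of <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  perm <- c(3, 1, 4, 2)
  out <- channel_attention(Of, omega = 0.7)
  out_p <- channel_attention(Of[, , perm], omega = 0.7)
  expect_equal(out_p, out[, , perm], tolerance = 1e-10)
})

test_that("spatial attention matches the exhaustive pair-sum oracle", {
  set.seed(3)
  Of <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  pr <- spatial_attention_params(8, seed = 5)
  expect_identical(spatial_attention(Of, pr, phi = 0), Of)
  res <- spatial_attention(Of, pr, phi = 0.7, return_weights = TRUE)
  expect_equal(unname(rowSums(res$E)), rep(1, 9), tolerance = 1e-12)
  M <- matrix(Of, 9, 8)
  Q <- sweep(M %*% pr$Wq, 2, pr$bq, `+`)
  S <- sweep(M %*% pr$Ws, 2, pr$bs, `+`)
  V <- sweep(M %*% pr$Wv, 2, pr$bv, `+`)
  U <- matrix(0, 9, 8)
  for (j in 1:9) {
    lg <- vapply(1:9, function(k) sum(Q[k, ] * S[j, ]), 0)
    e <- exp(lg - max(lg)); e <- e / sum(e)
    ws <- rep(0, ncol(V))
    for (k in 1:9) ws <- ws + e[k] * V[k, ]
    U[j, ] <- 0.7 * (ws %*% pr$Wo + pr$bo) + M[j, ]
  }
  expect_lt(max(abs(res$out - array(U, c(3, 3, 8)))), 1e-6)
})

test_that("spatial attention rejects too-narrow inputs", {
  expect_error(spatial_attention_params(4), "floor")
})

test_that("mixed attention wiring: parallel sum and serial compositions", {
  set.seed(4)
  Of <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  pr <- spatial_attention_params(8, seed = 2)
  expect_equal(mixed_attention(Of, "parallel", omega = 0, phi = 0, params = pr),
               2 * Of, tolerance = 1e-12)
  Z <- mixed_attention(Of, "parallel", omega = 0.4, phi = 0.6, params = pr)
  expect_equal(Z, channel_attention(Of, 0.4) + spatial_attention(Of, pr, 0.6),
               tolerance = 1e-12)
  # identity first stage: channel-then-spatial with omega = 0 is spatial alone
  expect_equal(mixed_attention(Of, "channel_then_spatial", omega = 0,
                               phi = 0.6, params = pr),
               spatial_attention(Of, pr, 0.6), tolerance = 1e-12)
  expect_error(mixed_attention(Of, "nonsense"), "arg")
})

test_that("non-finite activations are rejected before softmax", {
  Of <- array(rnorm(27), c(3, 3, 3))
  Of[1] <- NaN
  expect_error(channel_attention(Of, 0.5), "non-finite")
})
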