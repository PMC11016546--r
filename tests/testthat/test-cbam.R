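# Attention block: hand-computed tiny-tensor oracles, brute-force loop
# oracles, contractivity and ordering properties, and equivalence of the
# batched height-1 fast path with the generic implementation.

zero_channel_params <- function(C, rho = 1) {
  Ch <- C %/% rho
  channel_attention_params(matrix(0, Ch, C), rep(0, Ch), matrix(0, C, Ch), rep(0, C))
}

zero_spatial_params <- function(Z = 3) spatial_attention_params(array(0, c(Z, Z, 2)), 0)

rand_channel_params <- function(C, rho = 1, seed = 1) {
  set.seed(seed)
  Ch <- C %/% rho
  channel_attention_params(matrix(rnorm(Ch * C), Ch, C), rnorm(Ch),
                           matrix(rnorm(C * Ch), C, Ch), rnorm(C))
}

rand_spatial_params <- function(Z = 3, seed = 1) {
  set.seed(seed)
  spatial_attention_params(array(rnorm(Z * Z * 2), c(Z, Z, 2)), rnorm(1))
}

test_that("zero parameters give 0.5 gates everywhere and a 0.25-scaled block output", {
  set.seed(1)
  N <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  Lc <- channel_attention(N, zero_channel_params(3))
  expect_equal(dim(Lc), c(3L, 1L, 1L))
  expect_equal(as.numeric(Lc), rep(0.5, 3))
  Ls <- spatial_attention(N, zero_spatial_params())
  expect_equal(dim(Ls), c(1L, 4L, 5L))
  expect_equal(as.numeric(Ls), rep(0.5, 20))
  out <- cbam_block(N, zero_channel_params(3), zero_spatial_params())
  expect_equal(out, 0.25 * N)
})

test_that("channel attention reproduces the hand-evaluated two-channel example", {
  # identity perceptron (rho = 1): L_c = sigmoid(avg + max) per channel
  p <- channel_attention_params(diag(2), c(0, 0), diag(2), c(0, 0))
  N <- array(c(0, 1), c(2, 1, 1))
  Lc <- as.numeric(channel_attention(N, p))
  expect_equal(Lc, c(0.5, 1 / (1 + exp(-2))), tolerance = 1e-12)
  expect_equal(Lc[2], 0.8808, tolerance = 1e-4)
})

test_that("spatial attention reproduces the hand-evaluated 2x2 example", {
  # Z' = 1, kernel (1, 1), zero bias: pre-activation = mean-plane + max-plane
  p <- spatial_attention_params(array(1, c(1, 1, 2)), 0)
  N <- array(0, c(2, 2, 2))
  N[1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  N[2, , ] <- matrix(c(5, 6, 7, 8), 2, byrow = TRUE)
  Ls <- spatial_attention(N, p)
  expect_equal(Ls[1, , ], 1 / (1 + exp(-matrix(c(8, 10, 12, 14), 2, byrow = TRUE))))
})

test_that("gate application equals the brute-force triple loop", {
  set.seed(3)
  N <- array(rnorm(24), c(2, 3, 4))
  Lc <- runif(2)
  out_c <- apply_channel(Lc, N)
  Ls <- matrix(runif(12), 3, 4)
  out_s <- apply_spatial(Ls, N)
  for (c_i in 1:2) for (h in 1:3) for (w in 1:4) {
    expect_equal(out_c[c_i, h, w], Lc[c_i] * N[c_i, h, w])
    expect_equal(out_s[c_i, h, w], Ls[h, w] * N[c_i, h, w])
  }
  expect_identical(apply_channel(rep(1, 2), N), N)
  expect_identical(apply_spatial(matrix(1, 3, 4), N), N)
})

test_that("channel attention is equivariant under channel permutation", {
  set.seed(4)
  C <- 4
  p <- rand_channel_params(C, rho = 2, seed = 5)
  N <- array(rnorm(C * 3 * 3), c(C, 3, 3))
  perm <- c(3, 1, 4, 2)
  p_perm <- channel_attention_params(p$W1[, perm], p$b1, p$W2[perm, ], p$b2[perm])
  Lc <- channel_attention(N, p)
  Lc_perm <- channel_attention(N[perm, , , drop = FALSE], p_perm)
  expect_equal(as.numeric(Lc_perm), as.numeric(Lc)[perm])
})

test_that("the full block composes the four operations and is contractive", {
  set.seed(6)
  for (i in 1:25) {
    C <- sample(2:6, 1); H <- sample(1:4, 1); W <- sample(2:6, 1)
    N <- array(rnorm(C * H * W, sd = 2), c(C, H, W))
    p_c <- rand_channel_params(C, seed = i)
    p_s <- rand_spatial_params(seed = i + 100)
    out <- cbam_block(N, p_c, p_s)
    # composition oracle
    Np <- apply_channel(channel_attention(N, p_c), N)
    expect_equal(out, apply_spatial(spatial_attention(Np, p_s), Np))
    # both gates in (0,1) make the block contractive in magnitude
    expect_true(all(abs(out) <= abs(N) + 1e-12))
  }
})

test_that("attention is not invariant to adding a constant (regression counterexample)", {
  p_c <- rand_channel_params(3, seed = 7)
  p_s <- rand_spatial_params(seed = 8)
  set.seed(9)
  N <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  expect_false(isTRUE(all.equal(channel_attention(N, p_c),
                                channel_attention(N + 1, p_c))))
  expect_false(isTRUE(all.equal(spatial_attention(N, p_s),
                                spatial_attention(N + 1, p_s))))
})

test_that("channel-then-spatial ordering is observable", {
  p_c <- rand_channel_params(3, seed = 10)
  p_s <- rand_spatial_params(seed = 11)
  set.seed(12)
  N <- array(rnorm(3 * 2 * 4, sd = 3), c(3, 2, 4))
  forward <- cbam_block(N, p_c, p_s)
  # spatial first, then channel: a different composition
  Ns <- apply_spatial(spatial_attention(N, p_s), N)
  swapped <- apply_channel(channel_attention(Ns, p_c), Ns)
  expect_false(isTRUE(all.equal(forward, swapped)))
})

test_that("single-channel spatial pooling planes coincide", {
  set.seed(13)
  N <- array(rnorm(8), c(1, 2, 4))
  p <- zero_spatial_params()
  p$kernel[2, 2, 1] <- 1  # centre tap on the mean plane only
  q <- spatial_attention(N, p)
  p2 <- zero_spatial_params()
  p2$kernel[2, 2, 2] <- 1  # centre tap on the max plane only
  q2 <- spatial_attention(N, p2)
  expect_equal(q, q2)
})

test_that("invalid attention parameters are rejected", {
  expect_error(spatial_attention_params(array(0, c(4, 4, 2))),
               class = "ssvepr_validation_error")
  expect_error(spatial_attention_params(array(0, c(3, 3, 1))),
               class = "ssvepr_shape_error")
  expect_error(ssvepr:::init_channel_params(6, 4), class = "ssvepr_validation_error")
  expect_error(channel_attention(array(0, c(2, 2)), zero_channel_params(2)),
               class = "ssvepr_shape_error")
  expect_error(channel_attention(array(1, c(3, 2, 2)), zero_channel_params(2)),
               class = "ssvepr_shape_error")
})

test_that("the batched height-1 fast path matches the generic block per trial", {
  set.seed(14)
  C <- 6; Tn <- 17; B <- 4
  p_c <- rand_channel_params(C, rho = 2, seed = 15)
  p_s <- rand_spatial_params(Z = 5, seed = 16)
  A <- matrix(rnorm(C * Tn * B), C, Tn * B)
  fast <- ssvepr:::cbam_batched_forward(A, p_c, p_s, C, Tn, B)$out
  for (b in seq_len(B)) {
    cols <- (b - 1) * Tn + seq_len(Tn)
    N <- array(A[, cols], c(C, 1, Tn))
    expect_equal(fast[, cols], array(cbam_block(N, p_c, p_s), c(C, Tn)),
                 tolerance = 1e-12)
  }
})
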