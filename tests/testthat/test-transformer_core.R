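# Encoder building blocks against literal scalar-loop oracles.

test_that("scaled dot-product attention: degenerate and oracle cases", {
  set.seed(1)
  # n = 1: softmax of a scalar is 1, output is the single value row
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(rnorm(4), 1)
  expect_equal(unname(scaled_dot_attention(Q, K, V)[1, ]), V[1, ])
  # identical keys: uniform weights, every output row is the V column mean
  Q <- matrix(rnorm(12), 3); K <- matrix(rep(rnorm(4), each = 5), 5); V <- matrix(rnorm(20), 5)
  out <- scaled_dot_attention(Q, K, V)
  for (i in 1:3) expect_equal(unname(out[i, ]), colMeans(V), tolerance = 1e-12)
  # random case vs the double-loop oracle
  for (rep in 1:20) {
    Q <- matrix(rnorm(32), 4); K <- matrix(rnorm(48), 6); V <- matrix(rnorm(30), 6)
    expect_equal(unclass(scaled_dot_attention(Q, K, V)), oracle_scaled_dot_attention(Q, K, V),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("attention weights are convex and masked keys get zero weight", {
  set.seed(2)
  Q <- matrix(rnorm(24), 4); K <- matrix(rnorm(36), 6); V <- matrix(rnorm(12), 6)
  mask <- matrix(FALSE, 4, 6); mask[2, c(1, 3, 5)] <- TRUE
  out <- scaled_dot_attention(Q, K, V, mask)
  W <- attr(out, "weights")
  expect_equal(rowSums(W), rep(1, 4), tolerance = 1e-6)
  expect_true(all(W >= 0))
  expect_equal(W[2, c(1, 3, 5)], c(0, 0, 0))
  mask_all <- matrix(TRUE, 4, 6)
  expect_error(scaled_dot_attention(Q, K, V, mask_all), "every key masked")
})

test_that("multi-head attention reduces to a single head and matches the head loop", {
  set.seed(3)
  d <- 6; n <- 5
  X <- matrix(rnorm(n * d), n)
  # h = 1, Wo = identity: equals scaled_dot_attention of the projected inputs
  p1 <- list(Wq = list(matrix(rnorm(d * d), d)), Wk = list(matrix(rnorm(d * d), d)),
             Wv = list(matrix(rnorm(d * d), d)), Wo = diag(d))
  expect_equal(multi_head_attention(X, p1),
               unclass(scaled_dot_attention(X %*% p1$Wq[[1]], X %*% p1$Wk[[1]], X %*% p1$Wv[[1]])),
               tolerance = 1e-12, ignore_attr = TRUE)
  # random multi-head configs vs the per-head loop oracle
  for (rep in 1:10) {
    h <- sample(1:3, 1); dk <- sample(2:4, 1)
    p <- list(
      Wq = replicate(h, matrix(rnorm(d * dk), d), simplify = FALSE),
      Wk = replicate(h, matrix(rnorm(d * dk), d), simplify = FALSE),
      Wv = replicate(h, matrix(rnorm(d * dk), d), simplify = FALSE),
      Wo = matrix(rnorm(h * dk * d), h * dk)
    )
    expect_equal(multi_head_attention(X, p), oracle_multi_head(X, p), tolerance = 1e-6)
  }
})

test_that("self-attention without positions is permutation-equivariant", {
  set.seed(4)
  d <- 6; n <- 5
  X <- matrix(rnorm(n * d), n)
  p <- list(Wq = list(matrix(rnorm(d * 3), d)), Wk = list(matrix(rnorm(d * 3), d)),
            Wv = list(matrix(rnorm(d * 3), d)), Wo = matrix(rnorm(3 * d), 3))
  perm <- sample(n)
  out <- multi_head_attention(X, p)
  out_p <- multi_head_attention(X[perm, ], p)
  expect_equal(out_p[order(perm), ], out, tolerance = 1e-12)
})

test_that("positional encoding matches its closed form and the element loop", {
  d <- 16
  pe0 <- positional_encoding(0, d)
  expect_equal(pe0[seq(1, d, 2)], rep(0, d / 2)) # sin 0
  expect_equal(pe0[seq(2, d, 2)], rep(1, d / 2)) # cos 0
  expect_equal(positional_encoding(1, d)[1], sin(1), tolerance = 1e-12)
  for (pos in c(0, 1, 7, 33, 63)) {
    expect_equal(positional_encoding(pos, d), oracle_positional_encoding(pos, d),
                 tolerance = 1e-12)
  }
})

test_that("ffn: identity and dead-ReLU cases, and the loop oracle", {
  d <- 4
  p_id <- list(W1 = diag(d), b1 = rep(0, d), W2 = diag(d), b2 = rep(0, d))
  X <- matrix(abs(rnorm(12)), 3)
  expect_equal(ffn(X, p_id), X)
  # all-negative pre-activations: output collapses to b2
  p_dead <- list(W1 = diag(d), b1 = rep(-100, d), W2 = diag(d), b2 = 1:4)
  out <- ffn(matrix(rnorm(12, sd = 0.1), 3), p_dead)
  for (r in 1:3) expect_equal(unname(out[r, ]), as.numeric(1:4))
  set.seed(5)
  for (rep in 1:10) {
    p <- list(W1 = matrix(rnorm(4 * 7), 4), b1 = rnorm(7),
              W2 = matrix(rnorm(7 * 4), 7), b2 = rnorm(4))
    X <- matrix(rnorm(20), 5)
    expect_equal(ffn(X, p), oracle_ffn(X, p), tolerance = 1e-6)
  }
})

test_that("residual layer normalization centres, scales and handles constants", {
  set.seed(6)
  X <- matrix(rnorm(24), 4)
  # sublayer = -X collapses each row to the normalized zero vector: zeros
  expect_equal(residual_layernorm(X, -X), matrix(0, 4, 6))
  # constant rows normalize to zeros
  Xc <- matrix(5, 3, 6)
  expect_equal(residual_layernorm(Xc, matrix(0, 3, 6)), matrix(0, 3, 6))
  # per-position standardization before gain/bias
  S <- matrix(rnorm(24), 4)
  out <- residual_layernorm(X, S)
  expect_equal(rowMeans(out), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(out, 1, function(r) mean(r^2)), rep(1, 4), tolerance = 1e-3)
  gain <- rnorm(6); bias <- rnorm(6)
  expect_equal(residual_layernorm(X, S, gain, bias),
               oracle_residual_layernorm(X, S, gain, bias), tolerance = 1e-6)
})

test_that("encoder_forward composes embeddings, positions and blocks deterministically", {
  cfg0 <- encoder_config(d_model = 8, n_heads = 2, d_ff = 12, n_layers = 0, seed = 1)
  params0 <- init_encoder_params(cfg0, vocab_size = 9)
  ids <- c(1L, 4L, 7L)
  H0 <- encoder_forward(ids, cfg0, params0)
  want <- params0$E[ids, ] + t(vapply(0:2, positional_encoding, numeric(8), d_model = 8))
  expect_equal(H0, want)
  cfg <- encoder_config(d_model = 8, n_heads = 2, d_ff = 12, n_layers = 2, seed = 1)
  params <- init_encoder_params(cfg, vocab_size = 9)
  expect_identical(encoder_forward(ids, cfg, params), encoder_forward(ids, cfg, params))
  expect_error(encoder_forward(c(1L, 99L), cfg, params), "outside vocabulary")
  expect_error(encoder_forward(rep(1L, cfg$max_len + 1L), cfg, params), "max_len")
})

test_that("encoder outputs stay finite and shaped over random tiny configs", {
  for (seed in 1:25) {
    cfg <- encoder_config(d_model = 16, n_heads = 2, d_ff = 24, n_layers = 2, seed = seed)
    params <- init_encoder_params(cfg, vocab_size = 20)
    set.seed(seed)
    ids <- sample(20, sample(2:10, 1), replace = TRUE)
    H <- encoder_forward(ids, cfg, params)
    expect_identical(dim(H), c(length(ids), 16L))
    expect_true(all(is.finite(H)))
  }
})

test_that("encoder config enforces its invariants", {
  expect_error(encoder_config(d_model = 10, n_heads = 3), "divide")
  expect_error(encoder_config(dropout = 1), "dropout")
  expect_equal(encoder_config(d_model = 32, n_heads = 4)$d_k, 8L)
})
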