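# Graph-attention sublayer against scalar oracles, plus the fused model.

random_graph <- function(n) {
  A <- build_word_adjacency(dependency_parse(paste0("w", 1:n), random_tree_heads(n)))
  extra <- which(upper.tri(A) & A == 0)
  if (length(extra)) {
    add <- extra[sample.int(length(extra), min(2, length(extra)))]
    A[add] <- 1
    A <- pmax(A, t(A))
  }
  A
}

make_gat_layer <- function(d, K, hd = d) {
  list(
    W = replicate(K, matrix(rnorm(d * hd, sd = 0.5), d), simplify = FALSE),
    a = replicate(K, rnorm(2 * hd, sd = 0.5), simplify = FALSE),
    ln = list(gain = rep(1, d), bias = rep(0, d))
  )
}

test_that("gat_scores: zero attention vector, identical features, oracle equality", {
  set.seed(31)
  n <- 5; d <- 6
  A <- random_graph(n)
  h <- matrix(rnorm(n * d), n)
  lp <- make_gat_layer(d, 1)
  lp$a[[1]] <- rep(0, 2 * d)
  e0 <- gat_scores(h, lp, A)[[1]]
  expect_true(all(e0[A == 1] == 0))
  expect_true(all(e0[A == 0] == -Inf))
  # identical node features: every neighbour score identical
  h_same <- matrix(rep(rnorm(d), each = n), n)
  lp2 <- make_gat_layer(d, 1)
  e_same <- gat_scores(h_same, lp2, A)[[1]]
  expect_equal(length(unique(round(e_same[A == 1], 12))), 1L)
  # random graphs vs the literal scalar oracle
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    A <- random_graph(n)
    h <- matrix(rnorm(n * d), n)
    lp <- make_gat_layer(d, 2)
    e <- gat_scores(h, lp, A, negative_slope = 0.2)
    for (k in 1:2) {
      expect_equal(e[[k]], oracle_gat_scores(h, lp$W[[k]], lp$a[[k]], A, 0.2),
                   tolerance = 1e-6)
    }
  }
})

test_that("gat_attention normalizes over neighbourhoods only", {
  set.seed(32)
  # node with only a self-loop gets alpha_ii = 1
  A <- diag(1, 3); A[1, 2] <- A[2, 1] <- 1
  h <- matrix(rnorm(18), 3)
  lp <- make_gat_layer(6, 1)
  alpha <- gat_attention(gat_scores(h, lp, A), A)[[1]]
  expect_equal(alpha[3, 3], 1)
  expect_equal(alpha[3, 1:2], c(0, 0))
  # two neighbours with equal scores split 0.5 / 0.5
  e_eq <- list(matrix(c(0, 0, -Inf, 0, 0, -Inf, -Inf, -Inf, 0), 3, byrow = TRUE))
  a_eq <- gat_attention(e_eq, A)[[1]]
  expect_equal(a_eq[1, ], c(0.5, 0.5, 0))
  # random graphs vs masked-softmax loop oracle
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    A <- random_graph(n)
    h <- matrix(rnorm(n * 6), n)
    lp <- make_gat_layer(6, 2)
    e <- gat_scores(h, lp, A)
    al <- gat_attention(e, A)
    for (k in 1:2) {
      expect_equal(al[[k]], oracle_gat_attention(e[[k]], A), tolerance = 1e-6)
      expect_equal(rowSums(al[[k]]), rep(1, n), tolerance = 1e-6)
      expect_true(all(al[[k]][A == 0] == 0))
    }
  }
})

test_that("gat_aggregate: isolated node, symmetric clique, triple-loop oracle", {
  set.seed(33)
  d <- 6
  # K = 1, isolated node: h' = LeakyReLU(W h)
  A1 <- diag(1, 1)
  h1 <- matrix(rnorm(d), 1)
  lp <- make_gat_layer(d, 1)
  alpha1 <- gat_attention(gat_scores(h1, lp, A1), A1)
  got <- gat_aggregate(alpha1, h1, lp)
  want <- h1 %*% lp$W[[1]]
  want <- pmax(want, 0) + 0.2 * pmin(want, 0)
  expect_equal(got, want, tolerance = 1e-12)
  # clique with identical features: all outputs identical
  n <- 4
  Ac <- matrix(1, n, n)
  hc <- matrix(rep(rnorm(d), each = n), n)
  lpc <- make_gat_layer(d, 2)
  outc <- gat_aggregate(gat_attention(gat_scores(hc, lpc, Ac), Ac), hc, lpc)
  for (i in 2:n) expect_equal(outc[i, ], outc[1, ], tolerance = 1e-10)
  # random instances vs the triple-loop oracle
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    A <- random_graph(n)
    h <- matrix(rnorm(n * d), n)
    lp <- make_gat_layer(d, 2)
    al <- gat_attention(gat_scores(h, lp, A), A)
    expect_equal(gat_aggregate(al, h, lp),
                 oracle_gat_aggregate(al, h, lp$W, 0.2), tolerance = 1e-6)
  }
})

test_that("full GAT sublayer matches the composed scalar oracle across many seeds", {
  cfg <- gat_config(n_heads = 2, head_dim = 6, n_gat_layers = 1)
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(2:8, 1)
    A <- random_graph(n)
    h <- matrix(rnorm(n * 6), n)
    lp <- make_gat_layer(6, 2)
    lp$ln$gain <- rnorm(6, 1, 0.1); lp$ln$bias <- rnorm(6, 0, 0.1)
    got <- gat_sublayer(h, A, lp, cfg)
    e_or <- lapply(1:2, function(k) oracle_gat_scores(h, lp$W[[k]], lp$a[[k]], A, 0.2))
    al_or <- lapply(e_or, oracle_gat_attention, A = A)
    g_or <- oracle_gat_aggregate(al_or, h, lp$W, 0.2)
    want <- oracle_residual_layernorm(h, g_or, lp$ln$gain, lp$ln$bias)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("gat_sublayer degenerates correctly", {
  set.seed(34)
  n <- 4; d <- 6
  cfg <- gat_config(n_heads = 1, head_dim = d)
  A <- random_graph(n)
  x <- matrix(rnorm(n * d), n)
  # zeroed GAT path: layer-normalized x
  lp0 <- make_gat_layer(d, 1)
  lp0$W[[1]] <- matrix(0, d, d)
  expect_equal(gat_sublayer(x, A, lp0, cfg),
               residual_layernorm(x, matrix(0, n, d)), tolerance = 1e-12)
  # identity adjacency: row i depends only on x_i
  lp <- make_gat_layer(d, 1)
  out1 <- gat_sublayer(x, diag(1, n), lp, cfg)
  x2 <- x; x2[3, ] <- rnorm(d)
  out2 <- gat_sublayer(x2, diag(1, n), lp, cfg)
  expect_equal(out2[-3, ], out1[-3, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out2[3, ], out1[3, ])))
  # determinism
  expect_identical(gat_sublayer(x, A, lp, cfg), gat_sublayer(x, A, lp, cfg))
  expect_error(gat_sublayer(x, diag(1, n + 1), lp, cfg), "does not match")
})

test_that("concat multi-head form concatenates per-head ReLU outputs", {
  set.seed(35)
  n <- 4; d <- 6
  A <- random_graph(n)
  h <- matrix(rnorm(n * d), n)
  lp <- make_gat_layer(d, 2, hd = 3)
  al <- gat_attention(gat_scores(h, lp, A), A)
  out <- gat_aggregate(al, h, lp, concat_heads = TRUE)
  expect_equal(dim(out), c(n, d))
  expect_equal(out[, 1:3], pmax(al[[1]] %*% (h %*% lp$W[[1]]), 0))
})

test_that("bert_gat_classify emits a proper label distribution and checks alignment", {
  cfg <- encoder_config(d_model = 12, n_heads = 2, d_ff = 16, n_layers = 1, seed = 2)
  gcfg <- gat_config(n_heads = 2, head_dim = 12, n_gat_layers = 1)
  m <- new_model("bert_gat", cfg, vocab_size = 15, labels = c("x", "y", "z"),
                 gat_config = gcfg)
  set.seed(36)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    ids <- sample(15, n, replace = TRUE)
    A <- random_graph(n)
    p <- bert_gat_classify(ids, A, m)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_equal(names(p), c("x", "y", "z"))
  }
  expect_error(bert_gat_classify(c(1L, 2L), diag(1, 3), m, instance_id = "i9"),
               "mismatch for instance 'i9'")
})

test_that("zeroing the GAT path reduces the model to the plain encoder classifier plus a LayerNorm", {
  cfg <- encoder_config(d_model = 12, n_heads = 2, d_ff = 16, n_layers = 1, seed = 7)
  gcfg <- gat_config(n_heads = 1, head_dim = 12, n_gat_layers = 1)
  mg <- new_model("bert_gat", cfg, vocab_size = 15, labels = c("x", "y"), gat_config = gcfg)
  me <- new_model("encoder", cfg, vocab_size = 15, labels = c("x", "y"))
  # identical encoder weights (same seed); zero the GAT projection and
  # transplant the classification head
  mg$params$gat[[1]]$W[[1]][] <- 0
  mg$params$head <- me$params$head
  ids <- c(1L, 3L, 9L, 4L)
  H <- encoder_forward(ids, cfg, me$params)
  # the GAT model pools LayerNorm(H + 0); apply the same map to the plain path
  H_ln <- residual_layernorm(H, matrix(0, nrow(H), ncol(H)))
  s <- colMeans(H_ln)
  logits <- drop(s %*% me$params$head$Wc) + me$params$head$bc
  want <- exp(logits - max(logits)); want <- want / sum(want)
  got <- bert_gat_classify(ids, diag(1, 4), mg)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})
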