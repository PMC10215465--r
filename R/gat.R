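#' Graph-attention sublayer configuration
#'
#' @param n_heads Number of graph-attention heads `K`.
#' @param head_dim Per-head projection width. The fused (residual) sublayer
#'   averages head outputs, so `head_dim` must equal the model dimension;
#'   with `concat_heads = TRUE`, `n_heads * head_dim` must equal it.
#' @param negative_slope LeakyReLU slope for scores and output activation.
#' @param n_gat_layers Number of stacked graph-attention sublayers placed on
#'   top of the encoder stack.
#' @param concat_heads Use the concatenating multi-head form instead of the
#'   default averaged form (kept for ablation).
#' @return A `gat_config` list.
#' @export
gat_config <- function(n_heads = 2L, head_dim = 32L, negative_slope = 0.2,
                       n_gat_layers = 1L, concat_heads = FALSE) {
  stopifnot(n_heads >= 1L, head_dim >= 1L, n_gat_layers >= 1L,
            negative_slope > 0, negative_slope < 1)
  structure(
    list(
      n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
      negative_slope = negative_slope, n_gat_layers = as.integer(n_gat_layers),
      concat_heads = isTRUE(concat_heads)
    ),
    class = "gat_config"
  )
}

#' Initialize graph-attention parameters
#'
#' Per layer and head: a shared node projection `W` (`d_model x head_dim`)
#' and an attention vector `a` of length `2 * head_dim` scoring the
#' concatenated projected query/key node features; plus gain/bias for the
#' fused layer normalization.
#'
#' @param config A [gat_config()].
#' @param d_model Encoder hidden dimension.
#' @return Nested list: one element per GAT layer.
#' @export
init_gat_params <- function(config, d_model) {
  if (config$concat_heads) {
    stopifnot(config$n_heads * config$head_dim == d_model)
  } else {
    stopifnot(config$head_dim == d_model)
  }
  replicate(config$n_gat_layers, list(
    W = replicate(config$n_heads, rnorm_mat(d_model, config$head_dim), simplify = FALSE),
    a = replicate(config$n_heads, stats::rnorm(2L * config$head_dim, 0, 0.02), simplify = FALSE),
    ln = init_ln_params(d_model)
  ), simplify = FALSE)
}

#' Per-head graph-attention scores
#'
#' For every edge `(i, j)` of the graph, `e_ij = LeakyReLU(a^T [W h_i || W
#' h_j])`; non-neighbour entries carry `-Inf` so they are excluded from the
#' subsequent softmax.
#'
#' @param h `n x d_model` node feature matrix.
#' @param layer_params One layer's parameters from [init_gat_params()].
#' @param A Adjacency matrix over the `n` nodes.
#' @param negative_slope LeakyReLU slope.
#' @return List of `K` score matrices.
#' @export
gat_scores <- function(h, layer_params, A, negative_slope = 0.2) {
  stopifnot(nrow(A) == nrow(h))
  hd <- ncol(layer_params$W[[1]])
  lapply(seq_along(layer_params$W), function(k) {
    Wh <- h %*% layer_params$W[[k]]
    a <- layer_params$a[[k]]
    f1 <- drop(Wh %*% a[seq_len(hd)])
    f2 <- drop(Wh %*% a[hd + seq_len(hd)])
    e <- leaky_relu(outer(f1, f2, "+"), negative_slope)
    e[A == 0] <- -Inf
    e
  })
}

#' Normalized graph-attention coefficients
#'
#' Masked softmax of the scores over each node's one-hop neighbourhood
#' (which always includes the node itself via its self-loop):
#' `alpha_ij = exp(e_ij) / sum_{k in N_i} exp(e_ik)`.
#'
#' @param e List of per-head score matrices from [gat_scores()].
#' @param A Adjacency matrix the scores were computed on.
#' @return List of per-head coefficient matrices; each row sums to 1 and is
#'   zero off the neighbourhood.
#' @export
gat_attention <- function(e, A) {
  stopifnot(all(diag(A) == 1)) # self-loops guarantee nonempty neighbourhoods
  lapply(e, function(ek) {
    alpha <- softmax_rows(ek)
    alpha[A == 0] <- 0
    alpha
  })
}

#' Aggregate neighbour features under graph attention
#'
#' The averaged multi-head form: `h'_i = LeakyReLU((1/K) sum_k sum_{j in
#' N_i} alpha_ij^k W^k h_j)`. With `concat_heads`, per-head ReLU outputs
#' are concatenated instead.
#'
#' @param alpha Coefficients from [gat_attention()].
#' @param h Node features the scores were computed on.
#' @param layer_params Matching layer parameters.
#' @param negative_slope LeakyReLU slope.
#' @param concat_heads Use the concatenating form.
#' @return `n x d_model` matrix of updated node features.
#' @export
gat_aggregate <- function(alpha, h, layer_params, negative_slope = 0.2,
                          concat_heads = FALSE) {
  heads <- lapply(seq_along(alpha), function(k) {
    alpha[[k]] %*% (h %*% layer_params$W[[k]])
  })
  if (concat_heads) {
    do.call(cbind, lapply(heads, pmax, 0)) # sigma = ReLU per head, then concat
  } else {
    avg <- Reduce(`+`, heads) / length(heads)
    leaky_relu(avg, negative_slope)
  }
}

# Cached forward for one fused GAT sublayer: LayerNorm(x + GAT(x)).
gat_sublayer_fwd <- function(x, A, lp, cfg) {
  K <- cfg$n_heads
  hd <- cfg$head_dim
  heads <- vector("list", K)
  for (k in seq_len(K)) {
    Wh <- x %*% lp$W[[k]]
    a <- lp$a[[k]]
    f1 <- drop(Wh %*% a[seq_len(hd)])
    f2 <- drop(Wh %*% a[hd + seq_len(hd)])
    Epre <- outer(f1, f2, "+")
    e <- leaky_relu(Epre, cfg$negative_slope)
    e[A == 0] <- -Inf
    alpha <- softmax_rows(e)
    alpha[A == 0] <- 0
    heads[[k]] <- list(Wh = Wh, Epre = Epre, alpha = alpha, M = alpha %*% Wh)
  }
  if (cfg$concat_heads) {
    agg <- do.call(cbind, lapply(heads, function(hh) pmax(hh$M, 0)))
    G <- agg
  } else {
    agg <- Reduce(`+`, lapply(heads, `[[`, "M")) / K
    G <- leaky_relu(agg, cfg$negative_slope)
  }
  ln <- layer_norm_fwd(x + G, lp$ln$gain, lp$ln$bias)
  list(out = ln$out, x = x, A = A, heads = heads, agg = agg, ln = ln)
}

gat_sublayer_bwd <- function(cache, lp, cfg, dOut) {
  K <- cfg$n_heads
  hd <- cfg$head_dim
  lnb <- layer_norm_bwd(cache$ln, lp$ln$gain, dOut)
  dx <- lnb$dZ # residual path
  gW <- ga <- vector("list", K)
  if (cfg$concat_heads) {
    dAgg <- lnb$dZ
  } else {
    dG <- lnb$dZ
    dAgg <- dG * leaky_relu_grad(cache$agg, cfg$negative_slope)
  }
  nb_mask <- cache$A == 1
  for (k in seq_len(K)) {
    hc <- cache$heads[[k]]
    dM <- if (cfg$concat_heads) {
      dAgg[, (k - 1) * hd + seq_len(hd), drop = FALSE] * (hc$M > 0)
    } else {
      dAgg / K
    }
    dalpha <- dM %*% t(hc$Wh)
    dWh <- t(hc$alpha) %*% dM
    de <- softmax_rows_bwd(hc$alpha, dalpha) # zero off-neighbourhood (alpha = 0 there)
    dEpre <- de * leaky_relu_grad(hc$Epre, cfg$negative_slope)
    dEpre[!nb_mask] <- 0
    df1 <- rowSums(dEpre)
    df2 <- colSums(dEpre)
    a1 <- lp$a[[k]][seq_len(hd)]
    a2 <- lp$a[[k]][hd + seq_len(hd)]
    dWh <- dWh + outer(df1, a1) + outer(df2, a2)
    ga[[k]] <- c(drop(t(hc$Wh) %*% df1), drop(t(hc$Wh) %*% df2))
    gW[[k]] <- t(cache$x) %*% dWh
    dx <- dx + dWh %*% t(lp$W[[k]])
  }
  list(dx = dx, grads = list(W = gW, a = ga,
                             ln = list(gain = lnb$dgain, bias = lnb$dbias)))
}

#' Graph-attention sublayer with residual fusion
#'
#' `LayerNorm(x + GAT(x))`: the scores/coefficients/aggregation chain of
#' [gat_scores()], [gat_attention()] and [gat_aggregate()], wrapped by a
#' residual connection and layer normalization so tokens off the graph
#' (special tokens with self-loops only) retain their contextual features.
#'
#' @param x `n x d_model` hidden states.
#' @param A Adjacency matrix over the sequence.
#' @param layer_params One layer's parameters from [init_gat_params()].
#' @param config A [gat_config()].
#' @return `n x d_model` matrix.
#' @export
gat_sublayer <- function(x, A, layer_params, config) {
  if (nrow(A) != nrow(x)) stop("adjacency dimension ", nrow(A),
                               " does not match sequence length ", nrow(x))
  gat_sublayer_fwd(x, A, layer_params, config)$out
}
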