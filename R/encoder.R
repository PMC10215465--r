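#' Transformer encoder configuration
#'
#' @param d_model Model (embedding) dimension.
#' @param n_heads Number of attention heads; must divide `d_model`.
#' @param d_ff Inner dimension of the position-wise feed-forward network.
#' @param n_layers Number of encoder blocks.
#' @param dropout Dropout probability in `[0, 1)`; applied after each
#'   sublayer output before the residual add, and only in training mode.
#' @param max_len Maximum sequence length accepted by the encoder.
#' @param seed Seed from which all parameter initialization randomness flows.
#' @return An `encoder_config` list (per-head dimension `d_k` derived).
#' @export
encoder_config <- function(d_model = 32L, n_heads = 2L, d_ff = 64L,
                           n_layers = 2L, dropout = 0, max_len = 128L, seed = 0L) {
  stopifnot(d_model >= 1L, n_heads >= 1L, d_ff >= 1L, n_layers >= 0L,
            dropout >= 0, dropout < 1, max_len >= 1L)
  if (d_model %% n_heads != 0L) stop("n_heads must divide d_model (n_heads * d_k == d_model)")
  structure(
    list(
      d_model = as.integer(d_model), n_heads = as.integer(n_heads),
      d_k = as.integer(d_model %/% n_heads), d_ff = as.integer(d_ff),
      n_layers = as.integer(n_layers), dropout = dropout,
      max_len = as.integer(max_len), seed = as.integer(seed)
    ),
    class = "encoder_config"
  )
}

rnorm_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_attention_params <- function(d_model, n_heads, d_k) {
  list(
    Wq = replicate(n_heads, rnorm_mat(d_model, d_k), simplify = FALSE),
    Wk = replicate(n_heads, rnorm_mat(d_model, d_k), simplify = FALSE),
    Wv = replicate(n_heads, rnorm_mat(d_model, d_k), simplify = FALSE),
    Wo = rnorm_mat(n_heads * d_k, d_model)
  )
}

init_ffn_params <- function(d_model, d_ff) {
  list(W1 = rnorm_mat(d_model, d_ff), b1 = rep(0, d_ff),
       W2 = rnorm_mat(d_ff, d_model), b2 = rep(0, d_model))
}

init_ln_params <- function(d_model) list(gain = rep(1, d_model), bias = rep(0, d_model))

#' Initialize encoder parameters
#'
#' Learned token embeddings and all projections are drawn from a seeded
#' normal(0, 0.02); layer-norm gains start at 1 and biases at 0.
#'
#' @param config An [encoder_config()].
#' @param vocab_size Number of token ids.
#' @return Nested list of parameter matrices/vectors.
#' @export
init_encoder_params <- function(config, vocab_size) {
  set.seed(config$seed)
  layers <- replicate(config$n_layers, list(
    attn = init_attention_params(config$d_model, config$n_heads, config$d_k),
    ln1 = init_ln_params(config$d_model),
    ffn = init_ffn_params(config$d_model, config$d_ff),
    ln2 = init_ln_params(config$d_model)
  ), simplify = FALSE)
  list(E = rnorm_mat(vocab_size, config$d_model), layers = layers)
}

apply_dropout <- function(X, p) {
  if (p <= 0) return(list(X = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(X = X * mask, mask = mask)
}

# Forward with cached intermediates (training path). `ids` already include
# any special tokens; positional encodings are added to the embeddings.
encoder_fwd <- function(ids, cfg, params, train = FALSE) {
  n <- length(ids)
  if (n > cfg$max_len) {
    stop("sequence of length ", n, " exceeds max_len ", cfg$max_len,
         "; refusing to truncate silently")
  }
  drop_p <- if (train) cfg$dropout else 0
  X <- params$E[ids, , drop = FALSE] + pe_matrix(n, cfg$d_model)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    att <- mha_fwd(X, X, lp$attn)
    d1 <- apply_dropout(att$out, drop_p)
    ln1 <- layer_norm_fwd(X + d1$X, lp$ln1$gain, lp$ln1$bias)
    ff <- ffn_fwd(ln1$out, lp$ffn)
    d2 <- apply_dropout(ff$out, drop_p)
    ln2 <- layer_norm_fwd(ln1$out + d2$X, lp$ln2$gain, lp$ln2$bias)
    caches[[l]] <- list(att = att, ln1 = ln1, ff = ff, drop1 = d1$mask, drop2 = d2$mask)
    X <- ln2$out
    caches[[l]]$ln2 <- ln2
  }
  list(out = X, ids = ids, caches = caches)
}

encoder_bwd <- function(cache, cfg, params, dOut) {
  dX <- dOut
  grads <- list(E = NULL, layers = vector("list", cfg$n_layers))
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    cc <- cache$caches[[l]]
    ln2b <- layer_norm_bwd(cc$ln2, lp$ln2$gain, dX)
    dFF_out <- if (is.null(cc$drop2)) ln2b$dZ else ln2b$dZ * cc$drop2
    ffb <- ffn_bwd(cc$ff, lp$ffn, dFF_out)
    dLn1_out <- ln2b$dZ + ffb$dX
    ln1b <- layer_norm_bwd(cc$ln1, lp$ln1$gain, dLn1_out)
    dAtt_out <- if (is.null(cc$drop1)) ln1b$dZ else ln1b$dZ * cc$drop1
    attb <- mha_bwd(cc$att, lp$attn, dAtt_out)
    dX <- ln1b$dZ + attb$dXq + attb$dXkv
    grads$layers[[l]] <- list(
      attn = attb$grads,
      ln1 = list(gain = ln1b$dgain, bias = ln1b$dbias),
      ffn = ffb$grads,
      ln2 = list(gain = ln2b$dgain, bias = ln2b$dbias)
    )
  }
  # scatter embedding gradient by token id
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  for (i in seq_along(cache$ids)) {
    dE[cache$ids[i], ] <- dE[cache$ids[i], ] + dX[i, ]
  }
  grads$E <- dE
  grads
}

#' Run the transformer encoder
#'
#' Token embeddings plus sinusoidal positional encodings, followed by
#' `n_layers` blocks of multi-head self-attention and position-wise FFN,
#' each wrapped in a residual connection with layer normalization
#' (post-norm). Deterministic in evaluation mode.
#'
#' @param token_ids Integer vector of token ids (1-based into the
#'   embedding table).
#' @param config An [encoder_config()].
#' @param params Parameters from [init_encoder_params()].
#' @return `length(token_ids) x d_model` matrix of hidden states.
#' @export
encoder_forward <- function(token_ids, config, params) {
  if (any(token_ids < 1L | token_ids > nrow(params$E))) {
    stop("token id outside vocabulary [1, ", nrow(params$E), "]")
  }
  encoder_fwd(token_ids, config, params, train = FALSE)$out
}
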