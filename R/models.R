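# Assembled trainable models. Three kinds:
#   "encoder"     plain transformer encoder + linear/softmax head
#   "bert_gat"    encoder + stacked graph-attention sublayers + head
#   "t5_slim_dec" encoder + self-attention-free decoder (single learned
#                 query, cross-attention pooling) + linear/softmax head
#   "t5_ar_dec"   encoder + minimal standard autoregressive decoder
# All forward/backward passes are hand-derived and verified against
# finite differences in the test suite.

#' Create a trainable relation classification model
#'
#' @param kind One of `"encoder"`, `"bert_gat"`, `"t5_slim_dec"`,
#'   `"t5_ar_dec"`.
#' @param config An [encoder_config()]; its `seed` drives all parameter
#'   initialization.
#' @param vocab_size Input token vocabulary size.
#' @param labels Ordered character vector of class labels (the whole-label
#'   vocabulary for the decoder models).
#' @param gat_config A [gat_config()] (required for `"bert_gat"`).
#' @param pool Sequence summary fed to the classification head of the
#'   encoder models: `"mean"` (default) pools all final hidden states,
#'   `"cls"` uses the sequence-start token's vector.
#' @return A `deprex_model` list with `$params` ready for training.
#' @export
new_model <- function(kind = c("encoder", "bert_gat", "t5_slim_dec", "t5_ar_dec"),
                      config, vocab_size, labels, gat_config = NULL,
                      pool = c("mean", "cls")) {
  kind <- match.arg(kind)
  pool <- match.arg(pool)
  if (length(labels) == 0L) stop("label set must be non-empty")
  params <- init_encoder_params(config, vocab_size) # seeds the RNG
  d <- config$d_model
  L <- length(labels)
  if (kind == "bert_gat") {
    if (is.null(gat_config)) stop("bert_gat requires a gat_config")
    params$gat <- init_gat_params(gat_config, d)
  }
  if (kind %in% c("encoder", "bert_gat")) {
    params$head <- list(Wc = rnorm_mat(d, L), bc = rep(0, L))
  } else if (kind == "t5_slim_dec") {
    params$dec <- list(
      q = rnorm_mat(1, d), # learned start-token query embedding
      ca = init_attention_params(d, config$n_heads, config$d_k),
      ln1 = init_ln_params(d),
      ffn = init_ffn_params(d, config$d_ff),
      ln2 = init_ln_params(d),
      Wc = rnorm_mat(d, L), bc = rep(0, L)
    )
  } else { # t5_ar_dec: decoder vocab = labels + BOS + EOS
    V_dec <- L + 2L
    params$dec <- list(
      D = rnorm_mat(V_dec, d),
      sa = init_attention_params(d, config$n_heads, config$d_k),
      ln1 = init_ln_params(d),
      ca = init_attention_params(d, config$n_heads, config$d_k),
      ln2 = init_ln_params(d),
      ffn = init_ffn_params(d, config$d_ff),
      ln3 = init_ln_params(d),
      Wout = rnorm_mat(d, V_dec), bout = rep(0, V_dec)
    )
  }
  structure(
    list(kind = kind, config = config, gat_config = gat_config,
         labels = labels, pool = pool, vocab_size = vocab_size, params = params),
    class = "deprex_model"
  )
}

#' @export
print.deprex_model <- function(x, ...) {
  cat("<deprex_model ", x$kind, ">: d_model=", x$config$d_model, ", ",
      length(x$labels), " labels\n", sep = "")
  invisible(x)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---- encoder / bert_gat forward + backward -----------------------------

encoder_classifier_fwd <- function(model, ids, A = NULL, train = FALSE) {
  enc <- encoder_fwd(ids, model$config, model$params, train = train)
  H <- enc$out
  gat_caches <- NULL
  if (model$kind == "bert_gat") {
    if (is.null(A)) stop("bert_gat forward requires an adjacency matrix")
    if (nrow(A) != nrow(H)) {
      stop("adjacency dimension ", nrow(A), " does not match tokenized length ", nrow(H))
    }
    gat_caches <- vector("list", length(model$params$gat))
    for (l in seq_along(model$params$gat)) {
      gc <- gat_sublayer_fwd(H, A, model$params$gat[[l]], model$gat_config)
      gat_caches[[l]] <- gc
      H <- gc$out
    }
  }
  s <- if (model$pool == "mean") colMeans(H) else H[1, ]
  logits <- drop(s %*% model$params$head$Wc) + model$params$head$bc
  prob <- softmax_vec(logits)
  list(prob = prob, s = s, H = H, enc = enc, gat_caches = gat_caches)
}

encoder_classifier_bwd <- function(model, cache, y_idx) {
  p <- cache$prob
  dlogits <- p
  dlogits[y_idx] <- dlogits[y_idx] - 1
  hp <- model$params$head
  grads <- list(head = list(Wc = outer(cache$s, dlogits), bc = dlogits))
  ds <- drop(hp$Wc %*% dlogits)
  n <- nrow(cache$H)
  dH <- if (model$pool == "mean") {
    matrix(rep(ds / n, each = n), n, length(ds))
  } else {
    M <- matrix(0, n, length(ds)); M[1, ] <- ds; M
  }
  if (model$kind == "bert_gat") {
    grads$gat <- vector("list", length(model$params$gat))
    for (l in rev(seq_along(model$params$gat))) {
      gb <- gat_sublayer_bwd(cache$gat_caches[[l]], model$params$gat[[l]],
                             model$gat_config, dH)
      grads$gat[[l]] <- gb$grads
      dH <- gb$dx
    }
  }
  enc_grads <- encoder_bwd(cache$enc, model$config, model$params, dH)
  grads$E <- enc_grads$E
  grads$layers <- enc_grads$layers
  grads
}

# ---- slim decoder ------------------------------------------------------

#' Cross-attention from decoder queries over encoder outputs
#'
#' Scaled dot-product attention in which the query projections come from
#' the decoder side and key/value projections from the encoder output, so
#' each decoder position pools a convex combination of projected encoder
#' rows.
#'
#' @param query `m x d_model` matrix of decoder-side vectors.
#' @param encoder_out `n x d_model` encoder hidden states (`n >= 1`).
#' @param params Attention parameters (`Wq`, `Wk`, `Wv` head lists, `Wo`).
#' @return `m x d_model` matrix.
#' @export
cross_attention <- function(query, encoder_out, params) {
  if (nrow(encoder_out) == 0L) stop("encoder output is empty")
  mha_fwd(query, encoder_out, params)$out
}

slim_dec_fwd <- function(model, ids, train = FALSE) {
  enc <- encoder_fwd(ids, model$config, model$params, train = train)
  dp <- model$params$dec
  ca <- mha_fwd(dp$q, enc$out, dp$ca)
  ln1 <- layer_norm_fwd(dp$q + ca$out, dp$ln1$gain, dp$ln1$bias)
  ff <- ffn_fwd(ln1$out, dp$ffn)
  ln2 <- layer_norm_fwd(ln1$out + ff$out, dp$ln2$gain, dp$ln2$bias)
  logits <- drop(ln2$out %*% dp$Wc) + dp$bc
  prob <- softmax_vec(logits)
  list(prob = prob, enc = enc, ca = ca, ln1 = ln1, ff = ff, ln2 = ln2)
}

slim_dec_bwd <- function(model, cache, y_idx) {
  dp <- model$params$dec
  p <- cache$prob
  dlogits <- p
  dlogits[y_idx] <- dlogits[y_idx] - 1
  dWc <- outer(drop(cache$ln2$out), dlogits)
  dbc <- dlogits
  dLn2 <- matrix(drop(dp$Wc %*% dlogits), 1)
  ln2b <- layer_norm_bwd(cache$ln2, dp$ln2$gain, dLn2)
  ffb <- ffn_bwd(cache$ff, dp$ffn, ln2b$dZ)
  dLn1 <- ln2b$dZ + ffb$dX
  ln1b <- layer_norm_bwd(cache$ln1, dp$ln1$gain, dLn1)
  cab <- mha_bwd(cache$ca, dp$ca, ln1b$dZ)
  dq <- ln1b$dZ + cab$dXq
  enc_grads <- encoder_bwd(cache$enc, model$config, model$params, cab$dXkv)
  list(
    E = enc_grads$E, layers = enc_grads$layers,
    dec = list(
      q = dq, ca = cab$grads,
      ln1 = list(gain = ln1b$dgain, bias = ln1b$dbias),
      ffn = ffb$grads,
      ln2 = list(gain = ln2b$dgain, bias = ln2b$dbias),
      Wc = dWc, bc = dbc
    )
  )
}

#' Run the self-attention-free decoder head
#'
#' A single learned query pools the encoder output through cross-attention;
#' the pooled vector passes through a residual feed-forward sublayer and a
#' linear classifier with softmax over the whole-label vocabulary. There is
#' no input path for previously generated tokens, so the classification is
#' non-autoregressive by construction.
#'
#' @param encoder_out `n x d_model` encoder hidden states.
#' @param params The model's `dec` parameter list (see [new_model()]).
#' @param labels Ordered character vector of labels naming the output.
#' @return Named probability vector over `labels` (sums to 1).
#' @export
slim_decoder_forward <- function(encoder_out, params, labels) {
  if (length(labels) == 0L) stop("label set must be non-empty")
  if (nrow(encoder_out) == 0L) stop("encoder output is empty")
  ca <- mha_fwd(params$q, encoder_out, params$ca)
  ln1 <- layer_norm_fwd(params$q + ca$out, params$ln1$gain, params$ln1$bias)
  ff <- ffn_fwd(ln1$out, params$ffn)
  ln2 <- layer_norm_fwd(ln1$out + ff$out, params$ln2$gain, params$ln2$bias)
  logits <- drop(ln2$out %*% params$Wc) + params$bc
  stats::setNames(softmax_vec(logits), labels)
}

#' Select the output label from a probability vector
#'
#' Argmax with ties broken by the lowest label index, for determinism.
#'
#' @param prob Named probability vector (a valid distribution).
#' @return The selected label string.
#' @export
classify <- function(prob) {
  if (anyNA(prob) || any(is.nan(prob))) stop("probability vector contains NaN/NA")
  names(prob)[which.max(prob)]
}

# ---- autoregressive baseline decoder -----------------------------------

causal_mask <- function(m) outer(seq_len(m), seq_len(m), function(i, j) j > i)

# Teacher-forced decoder forward over a target label. Decoder input ids are
# [BOS, label]; targets are [label, EOS]. BOS = L+1, EOS = L+2.
ar_dec_fwd <- function(model, ids, y_idx, train = FALSE) {
  enc <- encoder_fwd(ids, model$config, model$params, train = train)
  dp <- model$params$dec
  L <- length(model$labels)
  dec_ids <- c(L + 1L, y_idx)
  m <- length(dec_ids)
  X <- dp$D[dec_ids, , drop = FALSE] + pe_matrix(m, model$config$d_model)
  sa <- mha_fwd(X, X, dp$sa, mask = causal_mask(m))
  ln1 <- layer_norm_fwd(X + sa$out, dp$ln1$gain, dp$ln1$bias)
  ca <- mha_fwd(ln1$out, enc$out, dp$ca)
  ln2 <- layer_norm_fwd(ln1$out + ca$out, dp$ln2$gain, dp$ln2$bias)
  ff <- ffn_fwd(ln2$out, dp$ffn)
  ln3 <- layer_norm_fwd(ln2$out + ff$out, dp$ln3$gain, dp$ln3$bias)
  logits <- add_rowvec(ln3$out %*% dp$Wout, dp$bout)
  probs <- t(apply(logits, 1, softmax_vec))
  targets <- c(y_idx, L + 2L)
  loss <- -sum(log(probs[cbind(seq_len(m), targets)]))
  list(loss = loss, probs = probs, targets = targets, dec_ids = dec_ids,
       enc = enc, sa = sa, ln1 = ln1, ca = ca, ln2 = ln2, ff = ff, ln3 = ln3)
}

ar_dec_bwd <- function(model, cache) {
  dp <- model$params$dec
  m <- nrow(cache$probs)
  dlogits <- cache$probs
  dlogits[cbind(seq_len(m), cache$targets)] <-
    dlogits[cbind(seq_len(m), cache$targets)] - 1
  dWout <- t(cache$ln3$out) %*% dlogits
  dbout <- colSums(dlogits)
  dLn3 <- dlogits %*% t(dp$Wout)
  ln3b <- layer_norm_bwd(cache$ln3, dp$ln3$gain, dLn3)
  ffb <- ffn_bwd(cache$ff, dp$ffn, ln3b$dZ)
  dLn2 <- ln3b$dZ + ffb$dX
  ln2b <- layer_norm_bwd(cache$ln2, dp$ln2$gain, dLn2)
  cab <- mha_bwd(cache$ca, dp$ca, ln2b$dZ)
  dLn1 <- ln2b$dZ + cab$dXq
  ln1b <- layer_norm_bwd(cache$ln1, dp$ln1$gain, dLn1)
  sab <- mha_bwd(cache$sa, dp$sa, ln1b$dZ)
  dX <- ln1b$dZ + sab$dXq + sab$dXkv
  dD <- matrix(0, nrow(dp$D), ncol(dp$D))
  for (i in seq_along(cache$dec_ids)) {
    dD[cache$dec_ids[i], ] <- dD[cache$dec_ids[i], ] + dX[i, ]
  }
  enc_grads <- encoder_bwd(cache$enc, model$config, model$params, cab$dXkv)
  list(
    E = enc_grads$E, layers = enc_grads$layers,
    dec = list(
      D = dD, sa = sab$grads,
      ln1 = list(gain = ln1b$dgain, bias = ln1b$dbias),
      ca = cab$grads,
      ln2 = list(gain = ln2b$dgain, bias = ln2b$dbias),
      ffn = ffb$grads,
      ln3 = list(gain = ln3b$dgain, bias = ln3b$dbias),
      Wout = dWout, bout = dbout
    )
  )
}

#' Greedy autoregressive decoding with the baseline decoder
#'
#' Standard left-to-right generation: starting from the beginning-of-
#' sequence token, each step runs the full decoder (causal self-attention,
#' cross-attention over the encoder output, feed-forward) and emits the
#' highest-probability next token, until the end token or `max_len`.
#'
#' @param model A `"t5_ar_dec"` [new_model()].
#' @param ids Encoder input token ids.
#' @param max_len Maximum number of generated tokens.
#' @return List with `tokens` (generated token strings, labels or
#'   `"</s>"`), `token_ids`, and `truncated` (`TRUE` when `max_len` was hit
#'   before the end token).
#' @export
decode_autoregressive_baseline <- function(model, ids, max_len = 4L) {
  stopifnot(model$kind == "t5_ar_dec", max_len >= 1L)
  enc <- encoder_fwd(ids, model$config, model$params, train = FALSE)
  dp <- model$params$dec
  L <- length(model$labels)
  vocab <- c(model$labels, "<s>", "</s>")
  dec_ids <- L + 1L # BOS
  out_ids <- integer()
  truncated <- TRUE
  for (step in seq_len(max_len)) {
    m <- length(dec_ids)
    X <- dp$D[dec_ids, , drop = FALSE] + pe_matrix(m, model$config$d_model)
    sa <- mha_fwd(X, X, dp$sa, mask = causal_mask(m))
    ln1 <- layer_norm_fwd(X + sa$out, dp$ln1$gain, dp$ln1$bias)
    ca <- mha_fwd(ln1$out, enc$out, dp$ca)
    ln2 <- layer_norm_fwd(ln1$out + ca$out, dp$ln2$gain, dp$ln2$bias)
    ff <- ffn_fwd(ln2$out, dp$ffn)
    ln3 <- layer_norm_fwd(ln2$out + ff$out, dp$ln3$gain, dp$ln3$bias)
    logits <- drop(ln3$out[m, , drop = FALSE] %*% dp$Wout) + dp$bout
    nxt <- which.max(logits)
    out_ids <- c(out_ids, nxt)
    dec_ids <- c(dec_ids, nxt)
    if (nxt == L + 2L) { truncated <- FALSE; break }
  }
  list(tokens = vocab[out_ids], token_ids = out_ids, truncated = truncated)
}

# ---- unified per-instance API used by the trainer ----------------------

model_forward <- function(model, ids, A = NULL, y_idx = NULL, train = FALSE) {
  switch(model$kind,
    encoder = ,
    bert_gat = encoder_classifier_fwd(model, ids, A, train = train),
    t5_slim_dec = slim_dec_fwd(model, ids, train = train),
    t5_ar_dec = ar_dec_fwd(model, ids, y_idx, train = train)
  )
}

model_loss_grads <- function(model, ids, A, y_idx, train = TRUE) {
  cache <- model_forward(model, ids, A, y_idx, train = train)
  if (model$kind == "t5_ar_dec") {
    list(loss = cache$loss, grads = ar_dec_bwd(model, cache))
  } else {
    loss <- -log(cache$prob[y_idx])
    grads <- if (model$kind == "t5_slim_dec") {
      slim_dec_bwd(model, cache, y_idx)
    } else {
      encoder_classifier_bwd(model, cache, y_idx)
    }
    list(loss = loss, grads = grads)
  }
}

# Predicted label for one instance.
model_predict_label <- function(model, ids, A = NULL) {
  if (model$kind == "t5_ar_dec") {
    out <- decode_autoregressive_baseline(model, ids)
    lab <- out$tokens[1]
    if (!lab %in% model$labels) model$labels[1] else lab # degenerate decode
  } else {
    cache <- model_forward(model, ids, A, train = FALSE)
    classify(stats::setNames(cache$prob, model$labels))
  }
}

#' Classify a relation instance with the graph-augmented encoder
#'
#' Runs the encoder, applies the stacked graph-attention sublayers under
#' the supplied adjacency matrix, summarizes the sequence (mean pooling or
#' the sequence-start token), and returns the softmax label distribution.
#'
#' @param token_ids Integer token ids (aligned with `A`).
#' @param A Adjacency matrix over the token positions.
#' @param model A `"bert_gat"` [new_model()].
#' @param instance_id Optional id used in alignment error messages.
#' @return Named probability vector over the model's labels.
#' @export
bert_gat_classify <- function(token_ids, A, model, instance_id = NULL) {
  stopifnot(model$kind == "bert_gat")
  if (nrow(A) != length(token_ids)) {
    stop("adjacency/sequence length mismatch",
         if (!is.null(instance_id)) paste0(" for instance '", instance_id, "'"),
         ": ", nrow(A), " vs ", length(token_ids))
  }
  cache <- encoder_classifier_fwd(model, token_ids, A, train = FALSE)
  stats::setNames(cache$prob, model$labels)
}
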