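#' Row-wise softmax
#'
#' @param S Numeric matrix of scores.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Backward of row-wise softmax: dS = P * (dP - rowSums(dP * P)).
softmax_rows_bwd <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`: every output row is a convex combination
#' of the rows of `V`, weighted by the similarity of the corresponding
#' query to each key.
#'
#' @param Q,K,V Numeric matrices; `Q` is `n_q x d_k`, `K` and `V` have
#'   `n_k` rows.
#' @param mask Optional logical `n_q x n_k` matrix marking disallowed key
#'   positions (`TRUE` = masked out).
#' @return `n_q x ncol(V)` matrix of attended values. The attention weight
#'   matrix is attached as attribute `"weights"`.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(S)))
    if (any(rowSums(!mask) == 0)) stop("some query has every key masked: softmax undefined")
    S[mask] <- -Inf
  }
  P <- softmax_rows(S)
  out <- P %*% V
  attr(out, "weights") <- P
  out
}

#' Sinusoidal positional encoding
#'
#' Even dimensions carry `sin(pos / 10000^(2i/d_model))` and odd dimensions
#' the matching cosine, so each position gets a unique, smoothly varying
#' fingerprint and relative offsets are linear functions of it.
#'
#' @param pos Non-negative integer position (0-based).
#' @param d_model Embedding dimension.
#' @return Numeric vector of length `d_model`.
#' @export
positional_encoding <- function(pos, d_model) {
  stopifnot(pos >= 0)
  d0 <- seq_len(d_model) - 1L # 0-based dimension index
  i <- d0 %/% 2L
  angle <- pos / 10000^(2 * i / d_model)
  ifelse(d0 %% 2L == 0L, sin(angle), cos(angle))
}

# Positional encoding table for positions 0..n-1 (rows), memoised: the
# training loop requests the same handful of (n, d_model) shapes millions
# of times.
.pe_cache <- new.env(parent = emptyenv())
pe_matrix <- function(n, d_model) {
  key <- paste0(d_model)
  tab <- .pe_cache[[key]]
  if (is.null(tab) || nrow(tab) < n) {
    rows <- max(n, 64L)
    tab <- t(vapply(seq_len(rows) - 1L, positional_encoding, numeric(d_model),
                    d_model = d_model))
    .pe_cache[[key]] <- tab
  }
  tab[seq_len(n), , drop = FALSE]
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = max(0, x W1 + b1) W2 + b2`: two linear maps with a ReLU in
#' between, applied independently at every sequence position.
#'
#' @param X `n x d_model` matrix.
#' @param params List with `W1` (`d_model x d_ff`), `b1`, `W2`
#'   (`d_ff x d_model`), `b2`.
#' @return Matrix of the same shape as `X`.
#' @export
ffn <- function(X, params) {
  ffn_fwd(X, params)$out
}

ffn_fwd <- function(X, p) {
  U <- add_rowvec(X %*% p$W1, p$b1)
  R <- pmax(U, 0)
  out <- add_rowvec(R %*% p$W2, p$b2)
  list(out = out, X = X, U = U, R = R)
}

ffn_bwd <- function(cache, p, dOut) {
  dR <- dOut %*% t(p$W2)
  dW2 <- t(cache$R) %*% dOut
  db2 <- colSums(dOut)
  dU <- dR * (cache$U > 0)
  dW1 <- t(cache$X) %*% dU
  db1 <- colSums(dU)
  dX <- dU %*% t(p$W1)
  list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Residual connection followed by layer normalization
#'
#' `LayerNorm(x + Sublayer(x))` with learned per-dimension gain and bias.
#' Each row is centred and scaled to unit variance (population variance,
#' epsilon-guarded) before the affine map; a constant row therefore
#' normalizes to zeros.
#'
#' @param X `n x d` input matrix.
#' @param sublayer_output Matrix of the same shape.
#' @param gain,bias Length-`d` vectors (default unit gain, zero bias).
#' @param eps Variance floor guarding constant rows.
#' @return Normalized `n x d` matrix.
#' @export
residual_layernorm <- function(X, sublayer_output, gain = rep(1, ncol(X)),
                               bias = rep(0, ncol(X)), eps = 1e-5) {
  stopifnot(identical(dim(X), dim(sublayer_output)))
  layer_norm_fwd(X + sublayer_output, gain, bias, eps)$out
}

layer_norm_fwd <- function(Z, gain, bias, eps = 1e-5) {
  mu <- rowMeans(Z)
  v <- rowMeans((Z - mu)^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (Z - mu) * inv_sd
  out <- add_rowvec(xhat * rep(gain, each = nrow(Z)), bias)
  list(out = out, xhat = xhat, inv_sd = inv_sd)
}

layer_norm_bwd <- function(cache, gain, dOut) {
  xhat <- cache$xhat
  dxhat <- dOut * rep(gain, each = nrow(dOut))
  dgain <- colSums(dOut * xhat)
  dbias <- colSums(dOut)
  dZ <- cache$inv_sd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dZ = dZ, dgain = dgain, dbias = dbias)
}

#' Multi-head attention
#'
#' Projects the inputs into `h` per-head query/key/value spaces, applies
#' [scaled_dot_attention()] in each, concatenates the head outputs and
#' mixes them with the output projection `W_O`.
#'
#' @param X `n x d_model` input (queries, keys and values all from `X`).
#' @param params List with `Wq`, `Wk`, `Wv` (each a list of `h` matrices
#'   `d_model x d_k`) and `Wo` (`h*d_k x d_model`).
#' @param mask Optional logical `n x n` matrix of disallowed key positions.
#' @return `n x d_model` matrix.
#' @export
multi_head_attention <- function(X, params, mask = NULL) {
  mha_fwd(X, X, params, mask)$out
}

# General attention block: queries from Xq, keys/values from Xkv.
mha_fwd <- function(Xq, Xkv, p, mask = NULL) {
  h <- length(p$Wq)
  heads <- vector("list", h)
  for (k in seq_len(h)) {
    Q <- Xq %*% p$Wq[[k]]
    K <- Xkv %*% p$Wk[[k]]
    V <- Xkv %*% p$Wv[[k]]
    S <- Q %*% t(K) / sqrt(ncol(Q))
    if (!is.null(mask)) S[mask] <- -Inf
    P <- softmax_rows(S)
    heads[[k]] <- list(Q = Q, K = K, V = V, P = P, H = P %*% V)
  }
  H <- do.call(cbind, lapply(heads, `[[`, "H"))
  list(out = H %*% p$Wo, Xq = Xq, Xkv = Xkv, heads = heads, H = H, mask = mask)
}

mha_bwd <- function(cache, p, dOut) {
  h <- length(p$Wq)
  dk <- ncol(cache$heads[[1]]$Q)
  dH <- dOut %*% t(p$Wo)
  dWo <- t(cache$H) %*% dOut
  dXq <- matrix(0, nrow(cache$Xq), ncol(cache$Xq))
  dXkv <- matrix(0, nrow(cache$Xkv), ncol(cache$Xkv))
  gWq <- gWk <- gWv <- vector("list", h)
  for (k in seq_len(h)) {
    hc <- cache$heads[[k]]
    dHk <- dH[, (k - 1) * dk + seq_len(dk), drop = FALSE]
    dP <- dHk %*% t(hc$V)
    dV <- t(hc$P) %*% dHk
    dS <- softmax_rows_bwd(hc$P, dP)
    if (!is.null(cache$mask)) dS[cache$mask] <- 0
    dQ <- dS %*% hc$K / sqrt(dk)
    dK <- t(dS) %*% hc$Q / sqrt(dk)
    gWq[[k]] <- t(cache$Xq) %*% dQ
    gWk[[k]] <- t(cache$Xkv) %*% dK
    gWv[[k]] <- t(cache$Xkv) %*% dV
    dXq <- dXq + dQ %*% t(p$Wq[[k]])
    dXkv <- dXkv + dK %*% t(p$Wk[[k]]) + dV %*% t(p$Wv[[k]])
  }
  list(dXq = dXq, dXkv = dXkv, grads = list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = dWo))
}

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope) (x > 0) + slope * (x <= 0)

# X + row vector / cheaper than sweep() in the training inner loop
add_rowvec <- function(X, b) X + rep(b, each = nrow(X))
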