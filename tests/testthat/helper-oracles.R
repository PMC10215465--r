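# Independent scalar-loop oracles for the neural building blocks. These
# implement the defining formulas literally, element by element, with no
# shared code path with the package's vectorized implementations.

# softmax(Q K^T / sqrt(d_k)) V, double loop
oracle_scaled_dot_attention <- function(Q, K, V) {
  n_q <- nrow(Q); n_k <- nrow(K); dk <- ncol(Q)
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q)) {
    s <- numeric(n_k)
    for (j in seq_len(n_k)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(n_k)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

oracle_multi_head <- function(X, p) {
  outs <- list()
  for (k in seq_along(p$Wq)) {
    outs[[k]] <- oracle_scaled_dot_attention(X %*% p$Wq[[k]], X %*% p$Wk[[k]], X %*% p$Wv[[k]])
  }
  do.call(cbind, outs) %*% p$Wo
}

oracle_positional_encoding <- function(pos, d_model) {
  v <- numeric(d_model)
  for (d0 in 0:(d_model - 1)) {
    i <- d0 %/% 2
    ang <- pos / 10000^(2 * i / d_model)
    v[d0 + 1] <- if (d0 %% 2 == 0) sin(ang) else cos(ang)
  }
  v
}

oracle_ffn <- function(X, p) {
  out <- matrix(0, nrow(X), ncol(p$W2))
  for (r in seq_len(nrow(X))) {
    u <- numeric(ncol(p$W1))
    for (j in seq_along(u)) u[j] <- max(0, sum(X[r, ] * p$W1[, j]) + p$b1[j])
    for (j in seq_len(ncol(p$W2))) out[r, j] <- sum(u * p$W2[, j]) + p$b2[j]
  }
  out
}

oracle_residual_layernorm <- function(X, S, gain, bias, eps = 1e-5) {
  Z <- X + S
  out <- matrix(0, nrow(Z), ncol(Z))
  for (r in seq_len(nrow(Z))) {
    z <- Z[r, ]
    mu <- mean(z)
    va <- mean((z - mu)^2)
    out[r, ] <- gain * (z - mu) / sqrt(va + eps) + bias
  }
  out
}

oracle_leaky <- function(x, s) if (x > 0) x else s * x

# e_ij = LeakyReLU(a^T [W h_i || W h_j]) on edges, one scalar at a time
oracle_gat_scores <- function(h, W, a, A, slope) {
  n <- nrow(h); hd <- ncol(W)
  e <- matrix(-Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] == 1) {
      whi <- as.numeric(h[i, , drop = FALSE] %*% W)
      whj <- as.numeric(h[j, , drop = FALSE] %*% W)
      e[i, j] <- oracle_leaky(sum(a * c(whi, whj)), slope)
    }
  }
  e
}

oracle_gat_attention <- function(e, A) {
  n <- nrow(e)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    ex <- exp(e[i, nb] - max(e[i, nb]))
    alpha[i, nb] <- ex / sum(ex)
  }
  alpha
}

# averaged multi-head aggregation, triple loop
oracle_gat_aggregate <- function(alphas, h, Ws, slope) {
  n <- nrow(h); hd <- ncol(Ws[[1]]); K <- length(Ws)
  out <- matrix(0, n, hd)
  for (i in seq_len(n)) {
    acc <- numeric(hd)
    for (k in seq_len(K)) {
      for (j in seq_len(n)) {
        if (alphas[[k]][i, j] != 0) {
          acc <- acc + alphas[[k]][i, j] * as.numeric(h[j, , drop = FALSE] %*% Ws[[k]])
        }
      }
    }
    out[i, ] <- vapply(acc / K, oracle_leaky, numeric(1), s = slope)
  }
  out
}

# ---- random fixtures ---------------------------------------------------

# Random single-rooted tree over n nodes (heads vector, 0 = root).
random_tree_heads <- function(n) {
  if (n == 1L) return(0L)
  perm <- sample.int(n)
  heads <- integer(n)
  heads[perm[1]] <- 0L
  for (i in 2:n) heads[perm[i]] <- perm[sample.int(i - 1L, 1L)]
  heads
}

# Random word->subword alignment over n_words (1-3 subwords each), with a
# leading and trailing special position.
random_alignment <- function(n_words) {
  sizes <- sample(1:3, n_words, replace = TRUE)
  pos <- 1L # position 1 is a special start token
  w2s <- vector("list", n_words)
  for (w in seq_len(n_words)) {
    w2s[[w]] <- pos + seq_len(sizes[w])
    pos <- pos + sizes[w]
  }
  n_total <- pos + 1L
  token_alignment(w2s, special_tokens = c(1L, n_total), n_model_tokens = n_total)
}

# Edge-enumeration oracle for the subword projection
oracle_project <- function(A_word, alignment) {
  n <- alignment$n_model_tokens
  A <- diag(1, n)
  w2s <- alignment$word_to_subwords
  for (u in seq_len(nrow(A_word))) for (v in seq_len(nrow(A_word))) {
    if (A_word[u, v] == 1) {
      for (i in w2s[[u]]) for (j in w2s[[v]]) A[i, j] <- 1
    }
  }
  for (u in seq_along(w2s)) for (i in w2s[[u]]) for (j in w2s[[u]]) A[i, j] <- 1
  A
}

# Tiny DDI-2013-style XML fixture written to a temp file; returns the path.
write_ddi_fixture <- function(sentences) {
  path <- tempfile(fileext = ".xml")
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', '<document id="d1">')
  for (s in sentences) {
    lines <- c(lines, sprintf('<sentence id="%s" text="%s">', s$id, s$text))
    for (e in s$entities) {
      lines <- c(lines, sprintf(
        '<entity id="%s" charOffset="%d-%d" type="drug" text="%s"/>',
        e$id, e$start, e$end_incl, e$text
      ))
    }
    for (p in s$pairs) {
      lines <- c(lines, sprintf(
        '<pair id="%s" e1="%s" e2="%s" ddi="%s"%s/>',
        p$id, p$e1, p$e2, p$ddi,
        if (!is.null(p$type)) sprintf(' type="%s"', p$type) else ""
      ))
    }
    lines <- c(lines, "</sentence>")
  }
  lines <- c(lines, "</document>")
  writeLines(lines, path)
  path
}
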