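#' Build the word-level adjacency matrix of a dependency parse
#'
#' Encodes the undirected dependency structure: `A[i, j] = 1` iff token `j`
#' is the head of token `i`, token `i` is the head of token `j`, or
#' `i == j` (self-loop). Dependency type labels are ignored, and the root's
#' head-0 link creates no edge (there is no virtual root node).
#'
#' @param parse A [dependency_parse()].
#' @return An `n x n` 0/1 matrix, symmetric with unit diagonal.
#' @export
build_word_adjacency <- function(parse) {
  stopifnot(inherits(parse, "dependency_parse"))
  n <- length(parse$tokens)
  A <- diag(1, n)
  for (i in seq_len(n)) {
    h <- parse$heads[i]
    if (h > 0L) {
      A[i, h] <- 1
      A[h, i] <- 1
    }
  }
  A
}

#' Describe the word-to-model-token alignment of a sequence
#'
#' Model tokenizers may split one parse word into several subword tokens and
#' add special positions (sequence start/end markers, pair separators). The
#' alignment records, for each word, the contiguous run of model-token
#' positions it occupies; all remaining positions must be listed as special.
#'
#' @param word_to_subwords List, one element per word, of integer vectors of
#'   model-token positions (1-based, each vector contiguous).
#' @param special_tokens Integer vector of model-token positions not covered
#'   by any word (sequence start/end tokens, markers).
#' @param n_model_tokens Total number of model-token positions.
#' @return A `token_alignment` list.
#' @export
token_alignment <- function(word_to_subwords, special_tokens = integer(), n_model_tokens) {
  covered <- c(unlist(word_to_subwords), special_tokens)
  if (anyDuplicated(covered)) stop("alignment assigns some model-token position twice")
  if (!setequal(covered, seq_len(n_model_tokens))) {
    stop("alignment must cover every model-token position exactly once")
  }
  for (v in word_to_subwords) {
    v <- as.integer(v)
    if (length(v) && any(diff(sort(v)) != 1L)) stop("subword positions of a word must be contiguous")
  }
  structure(
    list(
      word_to_subwords = lapply(word_to_subwords, as.integer),
      special_tokens = as.integer(special_tokens),
      n_model_tokens = as.integer(n_model_tokens)
    ),
    class = "token_alignment"
  )
}

#' Project a word-level adjacency matrix onto model tokens
#'
#' Every subword of word `w` inherits all of `w`'s word-level edges,
#' expanded to all subwords of each neighbouring word; all subwords of the
#' same word are fully interconnected; every model token carries a
#' self-loop. Special tokens (sequence start/end, pair markers) receive
#' self-loops only: the residual connection around the graph-attention
#' sublayer already carries their contextual features forward.
#'
#' @param A_word Word-level adjacency matrix from [build_word_adjacency()].
#' @param alignment A [token_alignment()] covering `nrow(A_word)` words.
#' @return A symmetric 0/1 matrix over model-token positions.
#' @export
project_to_subwords <- function(A_word, alignment) {
  stopifnot(inherits(alignment, "token_alignment"))
  n_words <- nrow(A_word)
  if (length(alignment$word_to_subwords) != n_words) {
    stop("alignment covers ", length(alignment$word_to_subwords),
         " words but adjacency has ", n_words)
  }
  n <- alignment$n_model_tokens
  A <- diag(1, n)
  for (w in seq_len(n_words)) {
    sw <- alignment$word_to_subwords[[w]]
    A[sw, sw] <- 1 # intra-word clique
    nb <- which(A_word[w, ] == 1)
    for (v in nb) {
      tv <- alignment$word_to_subwords[[v]]
      A[sw, tv] <- 1
      A[tv, sw] <- 1
    }
  }
  A
}

#' One-hop neighbourhood of a node
#'
#' The ascending indices `j` with `A[i, j] == 1`; by the self-loop
#' invariant this always contains `i` itself.
#'
#' @param A Adjacency matrix.
#' @param i Node index (1-based).
#' @return Integer vector of neighbour indices.
#' @export
neighbors <- function(A, i) {
  if (i < 1L || i > nrow(A)) stop("node index ", i, " out of range [1, ", nrow(A), "]")
  which(A[i, ] == 1)
}

# Internal sanity check used by randomized tests.
validate_adjacency <- function(A) {
  stopifnot(
    is.matrix(A), nrow(A) == ncol(A),
    all(A %in% c(0, 1)),
    all(diag(A) == 1),
    identical(A, t(A))
  )
  invisible(TRUE)
}
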