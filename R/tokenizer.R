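#' Build a whitespace tokenizer with character fallback
#'
#' Tiny from-scratch models use whitespace tokens with a frequency-capped
#' vocabulary. Out-of-vocabulary words fall back to per-character tokens
#' (every character seen in training is always in the vocabulary), which
#' also exercises the word-to-subword adjacency projection. Label strings
#' are added as atomic whole tokens so they are never split.
#'
#' @param texts Character vector of training texts (whitespace tokenized).
#' @param labels Character vector of label strings to add as whole tokens.
#' @param min_freq Words seen fewer than `min_freq` times are excluded from
#'   the word vocabulary (they fall back to characters).
#' @param max_words Cap on the number of word types kept (most frequent
#'   first, ties by lexical order).
#' @return A `tokenizer` object.
#' @export
build_tokenizer <- function(texts, labels = character(), min_freq = 1L, max_words = Inf) {
  words <- unlist(strsplit(texts, "\\s+"))
  words <- words[nzchar(words)]
  tab <- sort(table(words), decreasing = TRUE)
  keep <- names(tab)[tab >= min_freq]
  if (length(keep) > max_words) keep <- keep[seq_len(max_words)]
  chars <- sort(unique(unlist(strsplit(unique(words), "", fixed = TRUE))))
  vocab <- unique(c("[PAD]", "[UNK]", "[CLS]", "[SEP]", labels, keep, chars))
  structure(
    list(vocab = vocab, index = stats::setNames(seq_along(vocab), vocab)),
    class = "tokenizer"
  )
}

#' @export
print.tokenizer <- function(x, ...) {
  cat("<tokenizer>: ", length(x$vocab), " tokens\n", sep = "")
  invisible(x)
}

#' Tokenize one whitespace word into model-token ids
#'
#' In-vocabulary words map to a single id; others fall back to character
#' ids, with `[UNK]` for characters never seen.
#'
#' @param tokenizer A [build_tokenizer()] object.
#' @param word A single word (no whitespace).
#' @return Integer vector of token ids (length 1 for in-vocabulary words).
#' @export
tokenize_word <- function(tokenizer, word) {
  id <- tokenizer$index[word]
  if (!is.na(id)) return(unname(id))
  ids <- tokenizer$index[strsplit(word, "", fixed = TRUE)[[1]]]
  ids[is.na(ids)] <- tokenizer$index[["[UNK]"]]
  unname(ids)
}

#' Encode a text as a model-token sequence with word alignment
#'
#' Splits on whitespace, tokenizes each word with [tokenize_word()], and
#' wraps the sequence in `[CLS]` ... `[SEP]`. Words listed in
#' `special_words` (e.g. the pair markers `**` and `##`) are encoded as
#' single tokens and reported as special positions rather than as words, so
#' they receive self-loops only in the projected adjacency.
#'
#' @param tokenizer A [build_tokenizer()] object.
#' @param text Input text.
#' @param special_words Surface words treated as special positions.
#' @return List with `ids` (integer vector), `words` (the non-special
#'   words, in order) and `alignment` (a [token_alignment()] mapping those
#'   words to model-token positions).
#' @export
encode_text <- function(tokenizer, text, special_words = c("**", "##")) {
  words <- strsplit(trimws(text), "\\s+")[[1]]
  ids <- tokenizer$index[["[CLS]"]]
  specials <- 1L
  word_pos <- list()
  kept_words <- character()
  for (w in words) {
    tok <- tokenize_word(tokenizer, w)
    pos <- length(ids) + seq_along(tok)
    ids <- c(ids, tok)
    if (w %in% special_words) {
      specials <- c(specials, pos)
    } else {
      word_pos[[length(word_pos) + 1L]] <- pos
      kept_words <- c(kept_words, w)
    }
  }
  ids <- c(ids, tokenizer$index[["[SEP]"]])
  specials <- c(specials, length(ids))
  list(
    ids = unname(ids),
    words = kept_words,
    alignment = token_alignment(word_pos, specials, length(ids))
  )
}
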