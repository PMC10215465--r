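#' Split abstract text into sentences
#'
#' Deterministic rule-based splitter: a sentence boundary is a `.`, `?` or
#' `!` followed by whitespace and an uppercase letter or digit, unless the
#' word ending at the period is a known abbreviation (`e.g.`, `i.e.`,
#' `et al.`, `Fig.`, `vs.`, `Dr.`, `No.`, `ca.`) or a single capital
#' initial.
#'
#' @param text Character scalar.
#' @return Data frame with columns `text`, `start` (0-based offset of the
#'   sentence within `text`) and `end` (exclusive).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  abbrev <- c("e.g.", "i.e.", "al.", "Fig.", "Figs.", "vs.", "Dr.", "No.", "ca.", "approx.")
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bounds <- integer() # index (1-based) of last char of each sentence
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "?", "!")) {
      nxt <- i + 1L
      while (nxt <= n && chars[nxt] == " ") nxt <- nxt + 1L
      has_gap <- nxt > i + 1L
      starts_new <- nxt <= n && grepl("[A-Z0-9]", chars[nxt])
      if (has_gap && starts_new && chars[i] == ".") {
        # find the word ending here
        j <- i
        while (j > 1L && chars[j - 1L] != " ") j <- j - 1L
        word <- substr(text, j, i)
        initial <- grepl("^[A-Z]\\.$", word)
        if (word %in% abbrev || initial) {
          i <- i + 1L
          next
        }
      }
      if (has_gap && starts_new) bounds <- c(bounds, i)
    }
    i <- i + 1L
  }
  starts <- c(1L, vapply(bounds, function(b) {
    nxt <- b + 1L
    while (nxt <= n && chars[nxt] == " ") nxt <- nxt + 1L
    nxt
  }, integer(1)))
  ends <- c(bounds, n)
  keep <- starts <= ends
  data.frame(
    text = substring(text, starts[keep], ends[keep]),
    start = starts[keep] - 1L,
    end = ends[keep],
    stringsAsFactors = FALSE
  )
}

#' Read a ChemProt-style TSV corpus
#'
#' Three tab-separated files keyed by document id: `abstracts` with columns
#' (pmid, text); `entities` with (pmid, entity id, type, start, end, surface)
#' where type is `CHEMICAL` or `GENE`/`GENE-Y`/`GENE-N` and offsets are
#' 0-based end-exclusive into the document text; `relations` with
#' (pmid, CPR group, fine type, arg1, arg2) where the argument columns may
#' carry the `Arg1:T1` prefix form. Documents are split into sentences with
#' [split_sentences()]; entities are assigned to the sentence containing
#' them, and relations whose arguments land in different sentences are
#' dropped (their count is attached as attribute `n_cross_sentence`).
#' Entities spanning a sentence boundary are dropped with a warning.
#'
#' @param abstracts,entities,relations File paths.
#' @return List of [sentence_record()] objects (one per sentence, over all
#'   documents), with attribute `n_cross_sentence`.
#' @export
read_chemprot_tsv <- function(abstracts, entities, relations) {
  abs_df <- utils::read.delim(abstracts, header = FALSE, quote = "", stringsAsFactors = FALSE)
  if (ncol(abs_df) < 2L) stop("abstracts file needs at least (pmid, text) columns")
  names(abs_df)[1:2] <- c("pmid", "text")
  ent_df <- utils::read.delim(entities, header = FALSE, quote = "", stringsAsFactors = FALSE)
  if (ncol(ent_df) < 6L) stop("entities file needs (pmid, id, type, start, end, text) columns")
  names(ent_df)[1:6] <- c("pmid", "id", "type", "start", "end", "text")
  rel_df <- if (file.size(relations) > 0) {
    utils::read.delim(relations, header = FALSE, quote = "", stringsAsFactors = FALSE)
  } else {
    data.frame(pmid = character(), group = character(), fine = character(),
               arg1 = character(), arg2 = character())
  }
  if (nrow(rel_df) && ncol(rel_df) < 5L) {
    stop("relations file needs (pmid, group, fine type, arg1, arg2) columns")
  }
  if (nrow(rel_df)) names(rel_df)[1:5] <- c("pmid", "group", "fine", "arg1", "arg2")
  rel_df$arg1 <- sub("^Arg1:", "", rel_df$arg1)
  rel_df$arg2 <- sub("^Arg2:", "", rel_df$arg2)

  n_cross <- 0L
  records <- list()
  for (d in seq_len(nrow(abs_df))) {
    pmid <- as.character(abs_df$pmid[d])
    text <- abs_df$text[d]
    sents <- split_sentences(text)
    ents <- ent_df[as.character(ent_df$pmid) == pmid, , drop = FALSE]
    rels <- rel_df[as.character(rel_df$pmid) == pmid, , drop = FALSE]
    if (nrow(rels)) {
      bad <- setdiff(c(rels$arg1, rels$arg2), ents$id)
      if (length(bad)) {
        stop("relation in document '", pmid, "' references unknown entity id(s): ",
             paste(bad, collapse = ", "))
      }
    }
    ent_sentence <- rep(NA_integer_, nrow(ents))
    for (k in seq_len(nrow(ents))) {
      hit <- which(sents$start <= ents$start[k] & ents$end[k] <= sents$end)
      if (length(hit) == 1L) {
        ent_sentence[k] <- hit
      } else {
        warning("entity '", ents$id[k], "' in document '", pmid,
                "' spans a sentence boundary; dropped", call. = FALSE)
      }
    }
    for (s in seq_len(nrow(sents))) {
      in_s <- which(ent_sentence == s)
      mentions <- lapply(in_s, function(k) {
        entity_mention(
          id = ents$id[k],
          entity_class = if (ents$type[k] == "CHEMICAL") "CHEMICAL" else "GENE_PROTEIN",
          char_start = ents$start[k] - sents$start[s],
          char_end = ents$end[k] - sents$start[s],
          surface_text = ents$text[k]
        )
      })
      ids <- ents$id[in_s]
      keep_rel <- rels$arg1 %in% ids & rels$arg2 %in% ids
      gold <- data.frame(
        e1 = rels$arg1[keep_rel], e2 = rels$arg2[keep_rel],
        label = rels$fine[keep_rel], stringsAsFactors = FALSE
      )
      records[[length(records) + 1L]] <-
        sentence_record(paste0(pmid, ".s", s - 1L), sents$text[s], mentions, gold)
    }
    # cross-sentence: both args known and located, but in different sentences
    if (nrow(rels)) {
      loc1 <- ent_sentence[match(rels$arg1, ents$id)]
      loc2 <- ent_sentence[match(rels$arg2, ents$id)]
      n_cross <- n_cross + sum(!is.na(loc1) & !is.na(loc2) & loc1 != loc2)
    }
  }
  attr(records, "n_cross_sentence") <- n_cross
  records
}
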