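#' Create a dependency parse
#'
#' A single-rooted dependency tree over word tokens. Heads are 1-based; the
#' root token has head 0. Dependency relation labels are carried for
#' inspection but never used by the adjacency construction.
#'
#' @param tokens Character vector of word forms.
#' @param heads Integer vector of head indices (0 = root), same length.
#' @param deprels Optional character vector of relation labels.
#' @return A `dependency_parse` list.
#' @export
dependency_parse <- function(tokens, heads, deprels = NULL) {
  n <- length(tokens)
  heads <- as.integer(heads)
  if (length(heads) != n) stop("tokens and heads must have equal length")
  if (is.null(deprels)) deprels <- rep("dep", n)
  if (length(deprels) != n) stop("deprels must match tokens in length")
  if (n > 0L) {
    if (any(is.na(heads)) || any(heads < 0L) || any(heads > n)) {
      stop("head indices must lie in [0, ", n, "]")
    }
    n_root <- sum(heads == 0L)
    if (n_root != 1L) stop("parse must have exactly one root, found ", n_root)
  }
  structure(list(tokens = tokens, heads = heads, deprels = deprels),
            class = "dependency_parse")
}

#' @export
print.dependency_parse <- function(x, ...) {
  cat("<dependency_parse>: ", length(x$tokens), " token(s): ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read dependency parses from a CoNLL-U file
#'
#' One parse per sentence block. Comment lines, multiword-token ranges
#' (ids like `1-2`) and empty nodes (ids like `2.1`) are skipped. Only the
#' FORM, HEAD and DEPREL columns are retained.
#'
#' @param path Path to the CoNLL-U file.
#' @return List of [dependency_parse()] objects. Sentence ids from
#'   `# sent_id` comments, when present, are attached as names.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  parses <- list()
  ids <- character()
  tok <- character(); hd <- integer(); rel <- character(); sid <- NA_character_
  flush <- function() {
    if (length(tok)) {
      parses[[length(parses) + 1L]] <<- dependency_parse(tok, hd, rel)
      ids[length(parses)] <<- if (is.na(sid)) "" else sid
    }
    tok <<- character(); hd <<- integer(); rel <<- character(); sid <<- NA_character_
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", line))[[1]]
      if (length(m) == 2L) sid <- m[2]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L) stop("line ", i, " of '", path, "': expected >= 8 tab-separated fields")
    if (grepl("-", fields[1], fixed = TRUE) || grepl(".", fields[1], fixed = TRUE)) next
    head_val <- suppressWarnings(as.integer(fields[7]))
    if (is.na(head_val)) stop("line ", i, " of '", path, "': non-integer head field '", fields[7], "'")
    tok <- c(tok, fields[2]); hd <- c(hd, head_val); rel <- c(rel, fields[8])
  }
  flush()
  if (length(parses)) names(parses) <- ids
  parses
}

#' Write dependency parses to a CoNLL-U file
#'
#' Inverse of [read_conllu()] for the retained columns; unset columns are
#' written as `_`.
#'
#' @param parses List of [dependency_parse()] objects; names, when present,
#'   are emitted as `# sent_id` comments.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(parses, path) {
  out <- character()
  for (k in seq_along(parses)) {
    p <- parses[[k]]
    nm <- names(parses)[k]
    if (!is.null(nm) && nzchar(nm)) out <- c(out, paste0("# sent_id = ", nm))
    for (i in seq_along(p$tokens)) {
      out <- c(out, paste(i, p$tokens[i], "_", "_", "_", "_", p$heads[i],
                          p$deprels[i], "_", "_", sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
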