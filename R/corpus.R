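#' Create an entity mention
#'
#' Character offsets are 0-based and end-exclusive throughout the package,
#' so `surface_text` must equal `substr(text, char_start + 1, char_end)` of
#' the owning sentence.
#'
#' @param id Mention identifier, unique within its sentence.
#' @param entity_class `"DRUG"`, `"CHEMICAL"` or `"GENE_PROTEIN"`.
#' @param char_start,char_end 0-based offsets, end exclusive.
#' @param surface_text The mention's surface string.
#' @return An `entity_mention` list.
#' @export
entity_mention <- function(id, entity_class, char_start, char_end, surface_text) {
  entity_class <- match.arg(entity_class, c("DRUG", "CHEMICAL", "GENE_PROTEIN"))
  stopifnot(is.character(id), length(id) == 1L)
  char_start <- as.integer(char_start)
  char_end <- as.integer(char_end)
  if (is.na(char_start) || is.na(char_end) || char_start < 0L || char_start >= char_end) {
    stop("invalid offsets for mention '", id, "': [", char_start, ", ", char_end, ")")
  }
  structure(
    list(
      id = id, entity_class = entity_class,
      char_start = char_start, char_end = char_end,
      surface_text = surface_text
    ),
    class = "entity_mention"
  )
}

#' Create a sentence record
#'
#' A sentence with its annotated entity mentions and gold pairwise relations.
#' Overlapping mentions are resolved by dropping the shorter one (with a
#' warning), so downstream masking by character offset stays well defined.
#'
#' @param id Sentence identifier.
#' @param text Sentence text.
#' @param mentions List of [entity_mention()] objects.
#' @param gold_relations Data frame with columns `e1`, `e2`, `label` (may have
#'   zero rows). Each row references two distinct mention ids.
#' @return A `sentence_record` list.
#' @export
sentence_record <- function(id, text, mentions = list(), gold_relations = NULL) {
  if (is.null(gold_relations)) {
    gold_relations <- data.frame(
      e1 = character(), e2 = character(), label = character(),
      stringsAsFactors = FALSE
    )
  }
  ids <- vapply(mentions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate mention ids in sentence '", id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (m in mentions) {
    if (m$char_end > nchar(text)) {
      stop("mention '", m$id, "' offset outside sentence text (sentence '", id, "')")
    }
    slice <- substr(text, m$char_start + 1L, m$char_end)
    if (!identical(slice, m$surface_text)) {
      stop("mention '", m$id, "' surface text mismatch in sentence '", id,
           "': offsets give '", slice, "', annotation says '", m$surface_text, "'")
    }
  }
  mentions <- drop_overlapping_mentions(mentions, id)
  ids <- vapply(mentions, `[[`, "", "id")
  bad <- setdiff(c(gold_relations$e1, gold_relations$e2), ids)
  if (length(bad)) {
    stop("gold relation in sentence '", id, "' references unknown mention id(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(gold_relations$e1 == gold_relations$e2)) {
    stop("gold relation in sentence '", id, "' pairs a mention with itself")
  }
  structure(
    list(id = id, text = text, mentions = mentions, gold_relations = gold_relations),
    class = "sentence_record"
  )
}

#' @export
print.sentence_record <- function(x, ...) {
  cat("<sentence_record ", x$id, ">: ", length(x$mentions), " mention(s), ",
      nrow(x$gold_relations), " gold relation(s)\n", sep = "")
  invisible(x)
}

# Keep the longer of any two overlapping mentions; warn about the drop.
drop_overlapping_mentions <- function(mentions, sentence_id) {
  if (length(mentions) < 2L) return(mentions)
  keep <- rep(TRUE, length(mentions))
  for (i in seq_along(mentions)) {
    for (j in seq_along(mentions)) {
      if (i == j || !keep[i] || !keep[j]) next
      a <- mentions[[i]]; b <- mentions[[j]]
      if (a$char_start < b$char_end && b$char_start < a$char_end) {
        len_a <- a$char_end - a$char_start
        len_b <- b$char_end - b$char_start
        drop <- if (len_a < len_b) i else j
        warning("overlapping mentions in sentence '", sentence_id, "': dropping shorter mention '",
                mentions[[drop]]$id, "'", call. = FALSE)
        keep[drop] <- FALSE
      }
    }
  }
  mentions[keep]
}

# ---- DDI-2013-style XML ------------------------------------------------

# DDI entity subtypes (drug, brand, group, drug_n) all map to class DRUG.

#' Read a DDI-2013-style XML corpus file
#'
#' Expects `document/sentence` elements whose `entity` children carry
#' `id`, `charOffset` (`"start-end"`, end-inclusive as in the DDI-2013
#' distribution) and `text` attributes, and whose `pair` children carry
#' `e1`, `e2`, `ddi` (`"true"`/`"false"`) and, for interacting pairs, a
#' `type` attribute (`mechanism`, `effect`, `advise`, `int`). Annotated
#' interacting pairs become gold relations labelled `DDI-<type>`;
#' non-interacting drug pairs are materialized as `DDI-false` later, by
#' [generate_instances()].
#'
#' @param path Path to the XML file.
#' @return List of [sentence_record()] objects.
#' @export
read_ddi_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ", conditionMessage(e))
  )
  sentences <- xml2::xml_find_all(doc, ".//sentence")
  lapply(sentences, function(s) {
    sid <- xml2::xml_attr(s, "id")
    text <- xml2::xml_attr(s, "text")
    ents <- xml2::xml_find_all(s, "./entity")
    mentions <- lapply(ents, function(e) {
      off <- xml2::xml_attr(e, "charOffset")
      # Discontinuous offsets ("a-b;c-d") use the first span only.
      off1 <- strsplit(off, ";", fixed = TRUE)[[1]][1]
      se <- strsplit(off1, "-", fixed = TRUE)[[1]]
      if (length(se) != 2L || anyNA(suppressWarnings(as.integer(se)))) {
        stop("bad charOffset '", off, "' on entity '", xml2::xml_attr(e, "id"),
             "' in sentence '", sid, "'")
      }
      start <- as.integer(se[1])
      end_incl <- as.integer(se[2])
      entity_mention(
        id = xml2::xml_attr(e, "id"),
        entity_class = "DRUG",
        char_start = start,
        char_end = end_incl + 1L, # inclusive in the XML dialect, exclusive internally
        surface_text = substr(text, start + 1L, end_incl + 1L)
      )
    })
    pairs <- xml2::xml_find_all(s, "./pair")
    keep <- which(length(pairs) > 0 & xml2::xml_attr(pairs, "ddi") == "true")
    gold <- data.frame(
      e1 = as.character(xml2::xml_attr(pairs, "e1")[keep]),
      e2 = as.character(xml2::xml_attr(pairs, "e2")[keep]),
      label = if (length(keep)) paste0("DDI-", xml2::xml_attr(pairs, "type")[keep]) else character(),
      stringsAsFactors = FALSE
    )
    sentence_record(sid, text, mentions, gold)
  })
}

#' Write sentence records as DDI-2013-style XML
#'
#' Inverse of [read_ddi_xml()] up to the implicit `DDI-false` pairs: only
#' gold (interacting) pairs are emitted as `pair` elements with `ddi="true"`.
#'
#' @param records List of [sentence_record()] objects.
#' @param path Output file path.
#' @param document_id Id attribute for the enclosing `document` element.
#' @return `path`, invisibly.
#' @export
write_ddi_xml <- function(records, path, document_id = "d0") {
  doc <- xml2::xml_new_root("document", id = document_id)
  for (r in records) {
    s <- xml2::xml_add_child(doc, "sentence", id = r$id, text = r$text)
    for (m in r$mentions) {
      xml2::xml_add_child(
        s, "entity",
        id = m$id,
        charOffset = paste0(m$char_start, "-", m$char_end - 1L),
        type = tolower(m$entity_class),
        text = m$surface_text
      )
    }
    if (nrow(r$gold_relations)) {
      for (k in seq_len(nrow(r$gold_relations))) {
        xml2::xml_add_child(
          s, "pair",
          id = paste0(r$id, ".p", k - 1L),
          e1 = r$gold_relations$e1[k],
          e2 = r$gold_relations$e2[k],
          ddi = "true",
          type = sub("^DDI-", "", r$gold_relations$label[k])
        )
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
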