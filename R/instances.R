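#' Create a relation instance
#'
#' One candidate entity pair in one sentence: the unit of classification.
#'
#' @param sentence_id Owning sentence id.
#' @param pair Character vector of the two mention ids.
#' @param marked_text Sentence text with the two target mentions wrapped in
#'   separators (and, optionally, all mentions masked by class tokens).
#' @param label Gold label string.
#' @param scheme Scheme name (`"ddi5"`, `"ddi4"`, `"cpr_group"`, `"cpr_fine"`).
#' @return A `relation_instance` list.
#' @export
relation_instance <- function(sentence_id, pair, marked_text, label, scheme) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  structure(
    list(
      sentence_id = sentence_id, pair = as.character(pair),
      marked_text = marked_text, label = label, scheme = scheme
    ),
    class = "relation_instance"
  )
}

# Separator token for a target mention, by corpus convention:
# DDI wraps both drugs in "**"; ChemProt wraps the chemical in "##" and the
# gene/protein in "**" (assignment fixed by entity class for determinism).
marker_for <- function(entity_class, scheme_name) {
  if (startsWith(scheme_name, "ddi")) return("**")
  if (entity_class == "CHEMICAL") "##" else "**"
}

# Rebuild sentence text with target mentions wrapped (and optionally all
# mentions masked). Replacements run right-to-left by char_start so earlier
# offsets stay valid.
mark_sentence <- function(record, target_ids, scheme_name, mask_entities) {
  text <- record$text
  ord <- order(vapply(record$mentions, `[[`, 0L, "char_start"), decreasing = TRUE)
  for (m in record$mentions[ord]) {
    surf <- if (mask_entities) entity_mask_token(m$entity_class) else m$surface_text
    if (m$id %in% target_ids) {
      sep <- marker_for(m$entity_class, scheme_name)
      surf <- paste(sep, surf, sep)
    } else if (!mask_entities) {
      next
    }
    text <- paste0(
      substr(text, 1L, m$char_start),
      surf,
      substr(text, m$char_end + 1L, nchar(text))
    )
  }
  text
}

#' Generate classification instances from a sentence record
#'
#' Under the DDI schemes every unordered pair of drug mentions yields one
#' instance, labelled from the gold relations or `DDI-false` when
#' unannotated; `ddi4` then drops the `DDI-false` instances. Under the
#' ChemProt schemes each gold chemical-protein relation yields one instance
#' whose label (after group mapping for `cpr_group`) must lie in the
#' scheme's label set; unannotated pairs produce no instance unless
#' `include_negatives` is set, in which case they are labelled `"CPR-false"`.
#'
#' The two target mentions are wrapped in scheme-specific separators. With
#' `mask_entities`, every mention in the sentence is replaced by its class
#' token (`@DRUG$`, `@CHEM$`, `@PROT$`); non-target mentions are masked but
#' not separator-wrapped.
#'
#' @param record A [sentence_record()].
#' @param scheme A [label_scheme()].
#' @param mask_entities Replace every mention by its entity-class token.
#' @param include_negatives ChemProt only: also emit unannotated
#'   chemical-protein pairs, labelled `"CPR-false"`.
#' @return List of [relation_instance()] objects.
#' @export
generate_instances <- function(record, scheme, mask_entities = FALSE,
                               include_negatives = FALSE) {
  stopifnot(inherits(record, "sentence_record"), inherits(scheme, "label_scheme"))
  classes <- vapply(record$mentions, `[[`, "", "entity_class")
  if (length(classes) && !all(classes %in% scheme$entity_classes)) {
    stop("scheme '", scheme$name, "' cannot be applied to a record with entity classes ",
         paste(unique(setdiff(classes, scheme$entity_classes)), collapse = ", "),
         " (sentence '", record$id, "')")
  }
  gold <- record$gold_relations
  gold_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  gold_lut <- stats::setNames(gold$label, gold_key(gold$e1, gold$e2))
  out <- list()
  add <- function(e1, e2, label) {
    out[[length(out) + 1L]] <<- relation_instance(
      record$id, c(e1, e2),
      mark_sentence(record, c(e1, e2), scheme$name, mask_entities),
      label, scheme$name
    )
  }
  if (startsWith(scheme$name, "ddi")) {
    ids <- vapply(record$mentions, `[[`, "", "id")
    if (length(ids) >= 2L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq(i + 1L, length(ids))) {
          lab <- gold_lut[gold_key(ids[i], ids[j])]
          if (is.na(lab)) lab <- "DDI-false"
          if (scheme$name == "ddi4" && lab == "DDI-false") next
          add(ids[i], ids[j], unname(lab))
        }
      }
    }
  } else {
    for (k in seq_len(nrow(gold))) {
      lab <- gold$label[k]
      if (scheme$name == "cpr_group") lab <- map_cpr_group(lab)
      if (!lab %in% scheme$labels) next
      add(gold$e1[k], gold$e2[k], lab)
    }
    if (include_negatives) {
      chem <- vapply(record$mentions, `[[`, "", "id")[classes == "CHEMICAL"]
      prot <- vapply(record$mentions, `[[`, "", "id")[classes == "GENE_PROTEIN"]
      annotated <- gold_key(gold$e1, gold$e2)
      for (c_id in chem) for (p_id in prot) {
        if (!gold_key(c_id, p_id) %in% annotated) add(c_id, p_id, "CPR-false")
      }
    }
  }
  out
}

# ---- JSONL round trip --------------------------------------------------

#' Write relation instances to a JSONL file
#'
#' One JSON object per line with fields `sentence_id`, `pair`, `marked_text`,
#' `label`, `scheme`; UTF-8.
#'
#' @param instances List of [relation_instance()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(x) {
    jsonlite::toJSON(
      list(
        sentence_id = x$sentence_id, pair = x$pair,
        marked_text = x$marked_text, label = x$label, scheme = x$scheme
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read relation instances from a JSONL file
#'
#' @param path Input path.
#' @return List of [relation_instance()] objects.
#' @export
read_instances <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) stop("malformed JSONL at line ", i, " of '", path, "': ",
                               conditionMessage(e))
    )
    relation_instance(obj$sentence_id, obj$pair, obj$marked_text, obj$label, obj$scheme)
  })
}
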