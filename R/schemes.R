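#' Label schemes for relation classification
#'
#' The DDI-2013 shared task annotates four positive drug-drug interaction
#' classes (advise, effect, int, mechanism) plus an implicit negative class
#' `DDI-false` for co-occurring drug pairs without an annotated interaction.
#' ChemProt relations are evaluated either at the level of five CPR class
#' groups (CPR:3, CPR:4, CPR:5, CPR:6, CPR:9) or at the level of the 13
#' fine-grained relation types those groups contain.
#'
#' @param name One of `"ddi5"`, `"ddi4"`, `"cpr_group"`, `"cpr_fine"`.
#' @return A `label_scheme` object: a list with `name`, the ordered character
#'   vector `labels`, and `negative_label` (`NA` for schemes without one).
#' @examples
#' label_scheme("ddi4")$labels
#' @export
label_scheme <- function(name = c("ddi5", "ddi4", "cpr_group", "cpr_fine")) {
  name <- match.arg(name)
  ddi4 <- c("DDI-advise", "DDI-effect", "DDI-int", "DDI-mechanism")
  labels <- switch(name,
    ddi4 = ddi4,
    ddi5 = c(ddi4, "DDI-false"),
    cpr_group = c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9"),
    cpr_fine = unname(unlist(cpr_group_members()))
  )
  structure(
    list(
      name = name,
      labels = labels,
      negative_label = if (name == "ddi5") "DDI-false" else NA_character_,
      entity_classes = if (startsWith(name, "ddi")) "DRUG" else c("CHEMICAL", "GENE_PROTEIN")
    ),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme ", x$name, ">: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Evaluated CPR groups and their member relation types.
cpr_group_members <- function() {
  list(
    "CPR:3" = c("ACTIVATOR", "INDIRECT-UPREGULATOR", "UPREGULATOR"),
    "CPR:4" = c("DOWNREGULATOR", "INDIRECT-DOWNREGULATOR", "INHIBITOR"),
    "CPR:5" = c("AGONIST", "AGONIST-ACTIVATOR", "AGONIST-INHIBITOR"),
    "CPR:6" = "ANTAGONIST",
    "CPR:9" = c("SUBSTRATE", "SUBSTRATE_PRODUCT-OF", "PRODUCT-OF")
  )
}

#' Map a fine-grained ChemProt relation type to its CPR class group
#'
#' Only the five evaluated groups are covered; e.g. `"INHIBITOR"` belongs to
#' `"CPR:4"` and `"ANTAGONIST"` to `"CPR:6"`.
#'
#' @param fine_type Character vector of fine relation type strings.
#' @return Character vector of owning group labels (`"CPR:3"` ... `"CPR:9"`).
#' @export
map_cpr_group <- function(fine_type) {
  members <- cpr_group_members()
  lut <- stats::setNames(
    rep(names(members), lengths(members)),
    unlist(members)
  )
  out <- lut[fine_type]
  if (anyNA(out)) {
    bad <- unique(fine_type[is.na(out)])
    stop(
      "unknown ChemProt relation type(s): ", paste(bad, collapse = ", "),
      "; valid types: ", paste(names(lut), collapse = ", ")
    )
  }
  unname(out)
}

# Entity class -> masking placeholder token.
entity_mask_token <- function(entity_class) {
  lut <- c(DRUG = "@DRUG$", CHEMICAL = "@CHEM$", GENE_PROTEIN = "@PROT$")
  out <- lut[entity_class]
  if (anyNA(out)) stop("unknown entity class: ", paste(entity_class[is.na(out)], collapse = ", "))
  unname(out)
}
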