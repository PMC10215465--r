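# Corpus readers, label schemes, pair/instance construction.

test_that("label schemes carry the documented label sets", {
  expect_equal(label_scheme("ddi4")$labels,
               c("DDI-advise", "DDI-effect", "DDI-int", "DDI-mechanism"))
  expect_equal(label_scheme("ddi5")$labels,
               c("DDI-advise", "DDI-effect", "DDI-int", "DDI-mechanism", "DDI-false"))
  expect_equal(label_scheme("cpr_group")$labels,
               c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9"))
  expect_length(label_scheme("cpr_fine")$labels, 13L)
  expect_equal(label_scheme("ddi5")$negative_label, "DDI-false")
  expect_true(is.na(label_scheme("cpr_fine")$negative_label))
})

test_that("map_cpr_group maps fine types to their owning groups", {
  expect_equal(map_cpr_group("ACTIVATOR"), "CPR:3")
  expect_equal(map_cpr_group("ANTAGONIST"), "CPR:6")
  expect_equal(map_cpr_group("SUBSTRATE_PRODUCT-OF"), "CPR:9")
  expect_equal(map_cpr_group("INHIBITOR"), "CPR:4")
  expect_error(map_cpr_group("FRIEND"), "unknown ChemProt relation type")
  # surjectivity of the 13 fine labels onto the 5 groups
  expect_setequal(unique(map_cpr_group(label_scheme("cpr_fine")$labels)),
                  label_scheme("cpr_group")$labels)
})

test_that("read_ddi_xml parses sentences, mentions and gold pairs", {
  path <- write_ddi_fixture(list(list(
    id = "d1.s0",
    text = "aspirin enhances warfarin and heparin",
    entities = list(
      list(id = "e0", start = 0, end_incl = 6, text = "aspirin"),
      list(id = "e1", start = 17, end_incl = 24, text = "warfarin"),
      list(id = "e2", start = 30, end_incl = 36, text = "heparin")
    ),
    pairs = list(
      list(id = "p0", e1 = "e0", e2 = "e1", ddi = "true", type = "effect"),
      list(id = "p1", e1 = "e0", e2 = "e2", ddi = "true", type = "effect"),
      list(id = "p2", e1 = "e1", e2 = "e2", ddi = "false", type = NULL)
    )
  )))
  recs <- read_ddi_xml(path)
  expect_length(recs, 1L)
  expect_length(recs[[1]]$mentions, 3L)
  expect_equal(nrow(recs[[1]]$gold_relations), 2L)
  expect_equal(recs[[1]]$mentions[[2]]$surface_text, "warfarin")
  expect_equal(recs[[1]]$mentions[[2]]$char_start, 17L)
  expect_equal(recs[[1]]$mentions[[2]]$char_end, 25L) # exclusive internally
})

test_that("an empty document element yields an empty record list", {
  path <- tempfile(fileext = ".xml")
  writeLines('<document id="d0"></document>', path)
  expect_length(read_ddi_xml(path), 0L)
})

test_that("the three-drug mineral-oil sentence yields two mechanism relations", {
  # mirrors the worked example: mineral oil / fat-soluble vitamins /
  # vitamin d preparations with two pharmacokinetic (mechanism) pairs
  text <- "mineral oil reduces fat-soluble vitamins like vitamin d preparations"
  path <- write_ddi_fixture(list(list(
    id = "d2.s0", text = text,
    entities = list(
      list(id = "e0", start = 0, end_incl = 10, text = "mineral oil"),
      list(id = "e1", start = 20, end_incl = 39, text = "fat-soluble vitamins"),
      list(id = "e2", start = 46, end_incl = 67, text = "vitamin d preparations")
    ),
    pairs = list(
      list(id = "p0", e1 = "e0", e2 = "e1", ddi = "true", type = "mechanism"),
      list(id = "p1", e1 = "e0", e2 = "e2", ddi = "true", type = "mechanism"),
      list(id = "p2", e1 = "e1", e2 = "e2", ddi = "false", type = NULL)
    )
  )))
  recs <- read_ddi_xml(path)
  expect_equal(sort(recs[[1]]$gold_relations$label),
               c("DDI-mechanism", "DDI-mechanism"))
  # under ddi5 the unannotated pair materializes as DDI-false
  inst <- generate_instances(recs[[1]], label_scheme("ddi5"))
  expect_equal(sort(vapply(inst, `[[`, "", "label")),
               c("DDI-false", "DDI-mechanism", "DDI-mechanism"))
})

test_that("malformed XML and out-of-range offsets are rejected with context", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<document><sentence", bad)
  expect_error(read_ddi_xml(bad), "malformed XML")
  path <- write_ddi_fixture(list(list(
    id = "d3.s0", text = "tiny",
    entities = list(list(id = "e0", start = 0, end_incl = 20, text = "tiny")),
    pairs = list()
  )))
  expect_error(read_ddi_xml(path), "offset outside sentence text.*d3\\.s0")
})

make_chemprot_fixture <- function() {
  abs_p <- tempfile(fileext = ".tsv")
  ent_p <- tempfile(fileext = ".tsv")
  rel_p <- tempfile(fileext = ".tsv")
  text <- "Aspirin inhibits COX2 and thrombin here. Caffeine works alone."
  writeLines(paste("10001", text, sep = "\t"), abs_p)
  writeLines(c(
    paste("10001", "T1", "CHEMICAL", 0, 7, "Aspirin", sep = "\t"),
    paste("10001", "T2", "GENE-Y", 17, 21, "COX2", sep = "\t"),
    paste("10001", "T3", "GENE-N", 26, 34, "thrombin", sep = "\t"),
    paste("10001", "T4", "CHEMICAL", 41, 49, "Caffeine", sep = "\t")
  ), ent_p)
  writeLines(c(
    paste("10001", "CPR:4", "INHIBITOR", "Arg1:T1", "Arg2:T2", sep = "\t"),
    paste("10001", "CPR:4", "INHIBITOR", "Arg1:T4", "Arg2:T3", sep = "\t")
  ), rel_p)
  list(abstracts = abs_p, entities = ent_p, relations = rel_p)
}

test_that("read_chemprot_tsv splits sentences, assigns entities, drops cross-sentence relations", {
  fx <- make_chemprot_fixture()
  recs <- read_chemprot_tsv(fx$abstracts, fx$entities, fx$relations)
  expect_length(recs, 2L)
  expect_length(recs[[1]]$mentions, 3L) # 1 chemical + 2 genes in sentence 1
  expect_length(recs[[2]]$mentions, 1L)
  # in-sentence CPR:4 INHIBITOR retained as a gold fine-type relation
  expect_equal(recs[[1]]$gold_relations$label, "INHIBITOR")
  # the Caffeine..thrombin relation spans sentences: dropped and counted
  expect_equal(attr(recs, "n_cross_sentence"), 1L)
  expect_equal(sum(vapply(recs, function(r) nrow(r$gold_relations), 0L)), 1L)
  # offsets survive re-slicing (mention surfaces validated on construction)
  expect_equal(recs[[2]]$mentions[[1]]$surface_text, "Caffeine")
})

test_that("chemprot relations referencing unknown entities are an error", {
  fx <- make_chemprot_fixture()
  writeLines(paste("10001", "CPR:6", "ANTAGONIST", "Arg1:T9", "Arg2:T2", sep = "\t"),
             fx$relations)
  expect_error(read_chemprot_tsv(fx$abstracts, fx$entities, fx$relations),
               "unknown entity id")
})

test_that("the sentence splitter respects abbreviations and offsets", {
  s <- split_sentences("Dosing was 5 mg. Then e.g. twice daily. Effects seen.")
  expect_equal(nrow(s), 3L)
  expect_equal(s$text[2], "Then e.g. twice daily.")
  # offsets index back into the original text (0-based, end exclusive)
  txt <- "Dosing was 5 mg. Then e.g. twice daily. Effects seen."
  for (i in seq_len(nrow(s))) {
    expect_equal(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
  }
})

make_ddi_record <- function(m, gold = NULL) {
  drugs <- paste0("drug", LETTERS[seq_len(m)])
  text <- paste(c(drugs[1], "boosts", drugs[-1]), collapse = " ")
  starts <- cumsum(c(0L, nchar(c(drugs[1], "boosts", drugs[-1])) + 1L))
  pos <- c(1L, seq(3L, m + 1L))
  mentions <- lapply(seq_len(m), function(k) {
    entity_mention(paste0("e", k), "DRUG", starts[pos[k]],
                   starts[pos[k]] + nchar(drugs[k]), drugs[k])
  })
  sentence_record("s0", text, mentions, gold)
}

test_that("DDI instance generation enumerates unordered pairs with DDI-false backfill", {
  gold <- data.frame(e1 = c("e1", "e1"), e2 = c("e2", "e3"),
                     label = c("DDI-mechanism", "DDI-mechanism"))
  rec <- make_ddi_record(3, gold)
  inst5 <- generate_instances(rec, label_scheme("ddi5"))
  expect_length(inst5, 3L)
  expect_equal(sort(vapply(inst5, `[[`, "", "label")),
               c("DDI-false", "DDI-mechanism", "DDI-mechanism"))
  inst4 <- generate_instances(rec, label_scheme("ddi4"))
  expect_length(inst4, 2L) # DDI-false dropped under ddi4
  expect_length(generate_instances(make_ddi_record(1), label_scheme("ddi5")), 0L)
  # m = 5 with no gold relations: C(5,2) = 10 all-false instances
  inst_f <- generate_instances(make_ddi_record(5), label_scheme("ddi5"))
  expect_length(inst_f, choose(5, 2))
  expect_true(all(vapply(inst_f, `[[`, "", "label") == "DDI-false"))
})

test_that("pair-count invariant holds over randomized records", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(2:5, 1)
    ids <- paste0("e", seq_len(m))
    npos <- sample(0:choose(m, 2), 1)
    pairs <- t(combn(ids, 2))[sample(choose(m, 2), npos), , drop = FALSE]
    gold <- data.frame(e1 = pairs[, 1], e2 = pairs[, 2],
                       label = sample(label_scheme("ddi4")$labels, npos, replace = TRUE),
                       stringsAsFactors = FALSE)
    rec <- make_ddi_record(m, gold)
    expect_length(generate_instances(rec, label_scheme("ddi5")), m * (m - 1) / 2)
    expect_length(generate_instances(rec, label_scheme("ddi4")), npos)
  }
})

test_that("marking wraps exactly the two targets; masking is idempotent and class-aware", {
  gold <- data.frame(e1 = "e1", e2 = "e2", label = "DDI-effect")
  rec <- make_ddi_record(3, gold)
  inst <- generate_instances(rec, label_scheme("ddi5"), mask_entities = TRUE)
  for (x in inst) {
    words <- strsplit(x$marked_text, " ")[[1]]
    expect_equal(sum(words == "**"), 4L) # two wrapped spans
    expect_equal(sum(words == "@DRUG$"), 3L) # every mention masked
  }
  # masking an already-masked record is a no-op on the text
  words2 <- c("@DRUG$", "boosts", "@DRUG$", "@DRUG$")
  text2 <- paste(words2, collapse = " ")
  starts2 <- cumsum(c(0L, nchar(words2) + 1L))[c(1, 3, 4)]
  mentions2 <- lapply(seq_along(starts2), function(k) {
    entity_mention(paste0("e", k), "DRUG", starts2[k], starts2[k] + 6L, "@DRUG$")
  })
  rec2 <- sentence_record("s0", text2, mentions2, gold)
  inst2 <- generate_instances(rec2, label_scheme("ddi5"), mask_entities = TRUE)
  expect_equal(vapply(inst2, `[[`, "", "marked_text"),
               vapply(inst, `[[`, "", "marked_text"))
})

test_that("ChemProt instances follow gold relations and class-specific separators", {
  fx <- make_chemprot_fixture()
  recs <- read_chemprot_tsv(fx$abstracts, fx$entities, fx$relations)
  inst_f <- generate_instances(recs[[1]], label_scheme("cpr_fine"))
  expect_length(inst_f, 1L)
  expect_equal(inst_f[[1]]$label, "INHIBITOR")
  expect_match(inst_f[[1]]$marked_text, "## Aspirin ##", fixed = TRUE)
  expect_match(inst_f[[1]]$marked_text, "** COX2 **", fixed = TRUE)
  inst_g <- generate_instances(recs[[1]], label_scheme("cpr_group"))
  expect_equal(inst_g[[1]]$label, "CPR:4")
  # unannotated chemical-protein pairs yield no instance unless asked for
  expect_length(generate_instances(recs[[1]], label_scheme("cpr_fine"),
                                   include_negatives = TRUE), 2L)
  # scheme/record class mismatch is a configuration error
  expect_error(generate_instances(recs[[1]], label_scheme("ddi5")),
               "cannot be applied")
})

test_that("instances survive a JSONL round trip field-for-field", {
  empty <- tempfile(fileext = ".jsonl")
  write_instances(list(), empty)
  expect_length(read_instances(empty), 0L)
  set.seed(7)
  rec <- make_ddi_record(4)
  inst <- generate_instances(rec, label_scheme("ddi5"), mask_entities = sample(c(TRUE, FALSE), 1))
  path <- tempfile(fileext = ".jsonl")
  write_instances(inst, path)
  expect_length(readLines(path), length(inst))
  back <- read_instances(path)
  for (i in seq_along(inst)) expect_equal(unclass(back[[i]]), unclass(inst[[i]]))
  writeLines(c(readLines(path), "{not json"), path)
  expect_error(read_instances(path), "malformed JSONL at line 7")
})

test_that("DDI XML round trip preserves mention offsets exactly", {
  sp <- synthetic_spec(n_sentences = 6, seed = 5)
  recs <- generate_corpus(sp)$records
  path <- tempfile(fileext = ".xml")
  write_ddi_xml(recs, path)
  back <- read_ddi_xml(path)
  for (i in seq_along(recs)) {
    expect_equal(
      vapply(back[[i]]$mentions, `[[`, 0L, "char_start"),
      vapply(recs[[i]]$mentions, `[[`, 0L, "char_start")
    )
    expect_equal(
      vapply(back[[i]]$mentions, `[[`, 0L, "char_end"),
      vapply(recs[[i]]$mentions, `[[`, 0L, "char_end")
    )
  }
})

test_that("overlapping mentions drop the shorter with a warning", {
  text <- "mineral oil helps"
  expect_warning(
    rec <- sentence_record("s0", text, list(
      entity_mention("e1", "DRUG", 0L, 11L, "mineral oil"),
      entity_mention("e2", "DRUG", 0L, 7L, "mineral")
    )),
    "overlapping"
  )
  expect_equal(vapply(rec$mentions, `[[`, "", "id"), "e1")
})
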