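# Deterministic toy relation-extraction corpora with a planted structural
# signal. Each sentence is a templated clause pattern
#
#     [trigger e e] VERB [adverb?] [trigger'? e (e)]
#
# built directly as a projective dependency tree: the trigger token of the
# "real" group heads its two entity children and attaches to the root verb;
# all other entities attach to the root; a distractor trigger, when drawn,
# is a LEAF child of the root placed linearly in front of the remaining
# entities, so it mimics the surface shape of a real trigger group while
# lying on no entity-entity tree path. The gold label of a pair is the
# label of the unique trigger on the tree path between the two entities,
# or the negative label when the path carries none. The label is therefore
# recoverable from the structure but, whenever both a real and a distractor
# trigger are present, ambiguous from the token sequence alone.

#' Specification of a synthetic relation-extraction corpus
#'
#' @param n_sentences Number of sentences to generate.
#' @param entity_range Inclusive range of entities per sentence (2 to 4).
#' @param entity_count_probs Sampling weights for each entity count in
#'   `entity_range`.
#' @param scheme A [label_scheme()] with a negative label (default
#'   `"ddi5"`); positive labels take triggers from `trigger_lexicon`.
#' @param trigger_lexicon Named character vector mapping each positive
#'   label to its trigger word (injective).
#' @param off_path_distractor_rate Probability that a sentence with spare
#'   entities carries a conflicting off-path trigger.
#' @param mask_entities Emit instances with entity masking.
#' @param seed Seed; all generation randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_sentences = 200L,
                           entity_range = c(2L, 4L),
                           entity_count_probs = c(0.45, 0.25, 0.30),
                           scheme = label_scheme("ddi5"),
                           trigger_lexicon = c(
                             "DDI-advise" = "advised",
                             "DDI-effect" = "potentiates",
                             "DDI-int" = "interacts",
                             "DDI-mechanism" = "inhibits"
                           ),
                           off_path_distractor_rate = 0.5,
                           mask_entities = TRUE,
                           seed = 0L) {
  if (is.na(scheme$negative_label)) {
    stop("synthetic generation enumerates all pairs and needs a scheme with a negative label")
  }
  positives <- setdiff(scheme$labels, scheme$negative_label)
  if (!all(positives %in% names(trigger_lexicon))) {
    stop("trigger lexicon must cover every positive label; missing: ",
         paste(setdiff(positives, names(trigger_lexicon)), collapse = ", "))
  }
  if (anyDuplicated(trigger_lexicon[positives])) {
    stop("trigger lexicon must be injective")
  }
  stopifnot(off_path_distractor_rate >= 0, off_path_distractor_rate <= 1,
            entity_range[1] >= 2L, entity_range[2] <= 4L,
            length(entity_count_probs) == entity_range[2] - entity_range[1] + 1L)
  structure(
    list(
      n_sentences = as.integer(n_sentences), entity_range = as.integer(entity_range),
      entity_count_probs = entity_count_probs / sum(entity_count_probs),
      scheme = scheme, trigger_lexicon = trigger_lexicon[positives],
      off_path_distractor_rate = off_path_distractor_rate,
      mask_entities = isTRUE(mask_entities), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Closed surface lexicon ("drugA17"-style) so entity masking is meaningful.
synthetic_entity_names <- function() {
  as.vector(outer(LETTERS[1:10], 0:25, function(a, b) paste0("drug", a, b)))
}

neutral_verbs <- function() c("appears", "reported", "observed", "noted")
neutral_adverbs <- function() c("significantly", "rarely", "often")

#' Generate a synthetic corpus with a planted structural signal
#'
#' Produces sentence records, projective dependency parses and
#' classification instances (via [generate_instances()] under the spec's
#' scheme and masking flag). Fully deterministic given `spec$seed`. When
#' `out_dir` is given, also emits `corpus.xml` (DDI-style XML),
#' `corpus.conllu` and `instances.jsonl`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional output directory.
#' @return List with `records`, `parses` (named by sentence id) and
#'   `instances`.
#' @export
generate_corpus <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  positives <- names(spec$trigger_lexicon)
  counts <- seq(spec$entity_range[1], spec$entity_range[2])
  records <- list()
  parses <- list()
  for (s in seq_len(spec$n_sentences)) {
    sid <- sprintf("synth.s%d", s - 1L)
    m <- sample(counts, 1L, prob = spec$entity_count_probs)
    label <- sample(positives, 1L)
    trigger <- spec$trigger_lexicon[[label]]
    ents <- sample(synthetic_entity_names(), m)
    verb <- sample(neutral_verbs(), 1L)
    spare <- if (m > 2L) ents[seq(3L, m)] else character()
    distract <- m > 2L && stats::runif(1) < spec$off_path_distractor_rate
    d_word <- if (distract) {
      sample(unname(spec$trigger_lexicon[setdiff(positives, label)]), 1L)
    } else {
      character()
    }
    adverb <- if (stats::runif(1) < 0.3) sample(neutral_adverbs(), 1L) else character()
    real_left <- stats::runif(1) < 0.5
    # token layout; heads are filled in once positions are known
    real_grp <- c(trigger, ents[1:2]) # trigger heads its two entities
    other_grp <- c(d_word, spare)     # distractor is a leaf; entities hang off root
    left <- if (real_left) real_grp else other_grp
    right <- if (real_left) other_grp else real_grp
    tokens <- c(left, verb, adverb, right)
    root_pos <- length(left) + 1L
    heads <- integer(length(tokens))
    pos_of <- function(grp_start, offset) grp_start + offset - 1L
    fill_group <- function(heads, start, grp, is_real) {
      if (!length(grp)) return(heads)
      if (is_real) {
        heads[start] <- root_pos            # trigger -> root verb
        heads[start + 1L] <- start          # entity -> trigger
        heads[start + 2L] <- start          # entity -> trigger
      } else {
        for (k in seq_along(grp)) heads[start + k - 1L] <- root_pos
      }
      heads
    }
    heads <- fill_group(heads, 1L, left, real_left)
    heads[root_pos] <- 0L
    if (length(adverb)) heads[root_pos + 1L] <- root_pos
    right_start <- root_pos + length(adverb) + 1L
    heads <- fill_group(heads, right_start, right, !real_left)
    parse <- dependency_parse(tokens, heads)

    # entity mentions, in linear order
    ent_pos <- match(ents, tokens)
    ord <- order(ent_pos)
    ents_lin <- ents[ord]
    starts <- cumsum(c(0L, nchar(tokens) + 1L))[match(ents_lin, tokens)]
    text <- paste(tokens, collapse = " ")
    mentions <- lapply(seq_along(ents_lin), function(k) {
      entity_mention(paste0("e", k - 1L), spec$scheme$entity_classes[1],
                     starts[k], starts[k] + nchar(ents_lin[k]), ents_lin[k])
    })
    # gold relations from the planted rule: trigger lies on the path between
    # a pair iff at least one endpoint is one of its two children
    in_grp <- ents_lin %in% ents[1:2]
    gold <- data.frame(e1 = character(), e2 = character(), label = character(),
                       stringsAsFactors = FALSE)
    n_e <- length(ents_lin)
    for (i in seq_len(n_e - 1L)) for (j in seq(i + 1L, n_e)) {
      if (in_grp[i] || in_grp[j]) {
        gold <- rbind(gold, data.frame(
          e1 = paste0("e", i - 1L), e2 = paste0("e", j - 1L), label = label,
          stringsAsFactors = FALSE
        ))
      }
    }
    records[[s]] <- sentence_record(sid, text, mentions, gold)
    parses[[s]] <- parse
  }
  names(parses) <- vapply(records, `[[`, "", "id")
  instances <- unlist(lapply(records, generate_instances, scheme = spec$scheme,
                             mask_entities = spec$mask_entities),
                      recursive = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ddi_xml(records, file.path(out_dir, "corpus.xml"), document_id = "synth")
    write_conllu(parses, file.path(out_dir, "corpus.conllu"))
    write_instances(instances, file.path(out_dir, "instances.jsonl"))
  }
  list(records = records, parses = parses, instances = instances)
}

#' Word indices of a record's mentions within its (whitespace) token sequence
#'
#' @param record A [sentence_record()] whose text is space-tokenized.
#' @return Named integer vector: mention id -> 1-based word index.
#' @export
mention_word_indices <- function(record) {
  starts <- cumsum(c(0L, nchar(strsplit(record$text, " ", fixed = TRUE)[[1]]) + 1L))
  idx <- vapply(record$mentions, function(m) match(m$char_start, starts), integer(1))
  if (anyNA(idx)) stop("mention offsets of sentence '", record$id,
                       "' do not align with whitespace token boundaries")
  stats::setNames(idx, vapply(record$mentions, `[[`, "", "id"))
}

# Tree path between two nodes (1-based indices) as a vector of node indices.
tree_path <- function(heads, u, v) {
  chain <- function(x) {
    out <- x
    while (heads[x] != 0L) {
      x <- heads[x]
      out <- c(out, x)
    }
    out
  }
  cu <- chain(u)
  cv <- chain(v)
  lca <- cu[match(TRUE, cu %in% cv)]
  c(cu[seq_len(match(lca, cu))], rev(cv[seq_len(match(lca, cv) - 1L)]))
}

#' Rule-based reference labeller for the planted-structure task
#'
#' Walks the dependency-tree path between the two entity tokens and reads
#' off the unique trigger word on it; returns the negative label when the
#' path carries none. Two on-path triggers indicate a generation bug and
#' raise an error.
#'
#' @param parse A [dependency_parse()].
#' @param pair Integer vector of the two entity word indices (1-based).
#' @param lexicon Named character vector mapping labels to trigger words.
#' @param negative_label Label to return when no trigger lies on the path.
#' @return The label string.
#' @export
oracle_label <- function(parse, pair, lexicon, negative_label = "DDI-false") {
  stopifnot(length(pair) == 2L, all(pair >= 1L), all(pair <= length(parse$tokens)))
  path <- tree_path(parse$heads, pair[1], pair[2])
  on_path <- parse$tokens[path] %in% lexicon
  if (sum(on_path) > 1L) {
    stop("two triggers on the path between nodes ", pair[1], " and ", pair[2],
         ": generation bug")
  }
  if (!any(on_path)) return(negative_label)
  names(lexicon)[match(parse$tokens[path][on_path], lexicon)]
}
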