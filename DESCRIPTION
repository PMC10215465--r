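Package: deprex
Title: Dependency-Aware Transformer Models for Biomedical Relation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sentence-level drug-drug and chemical-protein relation
    classification. Reads DDI-2013-style XML and ChemProt-style TSV corpora,
    enumerates candidate entity pairs with marker/masking preprocessing,
    converts CoNLL-U dependency parses into token-level adjacency matrices,
    and implements two small trainable architectures from first principles:
    a transformer encoder augmented with a masked multi-head graph-attention
    sublayer over the dependency structure, and an encoder-decoder classifier
    whose decoder drops self-attention and pools the encoder output through
    cross-attention from a single learned query over a whole-label vocabulary.
    Includes seeded AdamW training with hand-derived gradients, micro, macro
    and weighted F1 evaluation with confusion matrices, and a deterministic
    synthetic-corpus generator that plants the relation signal on the
    dependency path between entity pairs so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
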