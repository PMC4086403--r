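Package: bioconc
Title: Interoperable Biomedical Annotation Formats and Dictionary-Based
    Concept Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Readers, writers and converters for two interoperable
    biomedical text annotation formats: the BioNLP shared-task standoff
    format (document text plus T/E/M/R/Equiv annotation lines) and BioC
    XML collections, including a faithful transcription scheme between
    the two that preserves entities, event structures, modifications,
    equivalences and coreference chains, and decorates BioC elements
    with type URIs. On top of the format layer, the package implements a
    dictionary-driven concept recognition stack for chemical, gene,
    disease and action-term curation: case-insensitive exact matching,
    approximate matching by stemmed-token overlap, silver-standard
    corpus generation with false-positive filtering against
    per-document gold concept lists, BIO token labelling for external
    sequence labellers, response normalization to preferred vocabulary
    names, document-level multilabel action-term classification, and
    micro-averaged concept-level evaluation. Seeded synthetic-corpus
    generators make the whole stack testable without external
    resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
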