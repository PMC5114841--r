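Package: taxamat
Title: Taxon-Character Matrices from Telegraphic Morphological Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds body-part measurement matrices from telegraphic
    taxonomic descriptions. Parses plain-text description batches into
    structure/character/value records using a glossary of categorized
    terms, handles compound measurement expressions (slash pairs, leg
    enumerations, multi-character lists, distance statements),
    consolidates records into taxon-character matrices with optional
    value inheritance and partonomy-based presence inference, supports
    auditable column edits (merge, rename, delete, split) with
    edit-effort accounting, and scores matrices against a gold standard
    with accuracy, precision, recall and F1. Includes a text normalizer
    that restores omitted measurement units and structure words, and a
    seeded generator of spider-style description corpora with known gold
    matrices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
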