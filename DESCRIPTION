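Package: abmine
Title: Mining Antibody NGS Repertoires for Matches to Therapeutic Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies sequence convergence between therapeutic antibody
    variable regions and naturally sourced next-generation sequencing (NGS)
    antibody repertoires. Implements a symmetric IMGT-positional sequence
    identity metric, IMGT CDR extraction with junction insertion codes,
    length-matched CDR-triplet and CDR-H3 comparison, exhaustive and indexed
    best-match search over OAS-style numbered repertoires, classification of
    therapeutic antibodies by their international nonproprietary name (INN)
    suffixes, threshold summarization and per-type stratification, and a
    seeded V(D)J-style repertoire simulator with somatic-hypermutation-like
    noise, sequencing error and unproductive-sequence injection for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
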