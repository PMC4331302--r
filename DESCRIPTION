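Package: nemapcr
Title: In-Silico PCR and Primer Specificity for Nematode Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates and simulates a nematode-selective semi-nested
    SSU (18S rDNA) metabarcoding assay. Provides IUPAC-aware
    primer-template matching with a 3'-terminal mismatch rule,
    per-position conservation and dot-notation consensus tables of a
    primer across taxon groups, amplicon prediction for primer pairs and
    for the semi-nested tagged strategy (including pyrosequencing
    adapter and MID arithmetic), and a seeded mock-community generator
    with substitution-error read simulation so the whole pipeline is
    testable without external reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
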