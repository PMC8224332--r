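Package: aqpscan
Title: Aquaporin Gene Family Identification, Classification and Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and comparative analysis of plant aquaporin (AQP)
    gene families. Detects AQP-like candidates from dual NPA motifs and
    hydropathy-predicted transmembrane helices, builds a progressive multiple
    alignment, extracts the ar/R selectivity filter anchored on the NPA motif
    columns, classifies subfamilies and subgroups (signature matching with a
    nearest-neighbour fallback and a neighbor-joining tree), profiles the
    14-position AQP domain motif architecture, detects tandem arrays and dates
    duplications with NG86 Ka/Ks, and clusters stress-response expression
    profiles with fuzzy c-means followed by Fisher/Benjamini-Hochberg GO
    enrichment. Ships seeded synthetic-data generators with ground-truth
    records and fixtures transcribed from a published pepper AQP family table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
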