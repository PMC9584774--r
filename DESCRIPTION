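Package: grmhor
Title: Global Repeat Map Detection and Annotation of Higher-Order Repeats
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects tandem repeats and higher-order repeat (HOR) structure in
    DNA sequences with the global repeat map (GRM) method: recurrence-distance
    spectra over the complete K-string ensemble, repeat-length peak detection,
    repeat-copy segmentation, iterative consensus construction, and discovery
    of internal monomer substructure. Classifies monomer segments against
    consensus monomers by edit (Levenshtein) distance, calls canonical 3mer
    HOR copies, groups them into tandem arrays, and computes inter-copy and
    intra-copy divergence statistics. Ships a seeded simulator of planted HOR
    arrays (three ~1.6-kb monomer types at ~18% mutual divergence, HOR copies
    at ~1.6% mutual divergence, embedded in random flanks) for validation, and
    a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
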