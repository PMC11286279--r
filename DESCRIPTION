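Package: multibwt
Title: Burrows-Wheeler Transform Variants for String Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs, inverts, and compares the six Burrows-Wheeler
    transform (BWT) variants in use for collections of strings: the
    extended BWT (eBWT) under the omega-order, the dollar-eBWT, the
    multidollar BWT, its colexicographic and run-minimizing (optimal)
    special cases, and the concatenation BWT. Includes the analysis
    machinery relating the variants: interesting intervals, per-interval
    run-count bounds, dataset variability, and pairwise Hamming and edit
    distances, together with brute-force reference implementations and a
    seeded synthetic collection generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
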