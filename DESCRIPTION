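Package: hybriclass
Title: DNA Instance-Based Image Classification via Non-Specific
    Hybridization Yields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes grayscale digit images into 59-nt DNA sequences with a
    trained neural encoder so that visually similar images map to strongly
    hybridizing sequences, then classifies a query image by the class whose
    "tube" of instance sequences gives the highest summed hybridization
    yield against the query's reverse complement. Includes a built-in
    two-state nearest-neighbor thermodynamic engine for duplex free energy
    and equilibrium yield (with a pluggable external backend), a sequence-pair
    corpus generator for training the convolutional yield predictor, a
    LeNet-5-style feature extractor, a synthetic digit-glyph corpus
    generator, and an instance-based classifier with evaluation and
    neighbor-retrieval utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
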