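Package: profkernel
Title: Fast Profile String Kernel for Multi-Class Protein Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains and applies profile-kernel support vector machine
    classifiers for proteins. Each protein is represented by a
    position-specific scoring profile; the kernel counts conserved k-mers
    shared between profiles, enumerated by a depth-first traversal of the
    20-ary k-mer trie with cumulative-score pruning. Provides a sparse
    coordinate-list buffer with self-multiplication for Gram-matrix
    construction, block-wise (split/assemble) kernel computation for
    parallel training, explicit extraction of SVM normal vectors in the
    20^k feature space via a single trie traversal, batch scoring of
    query profiles against many SVMs at once, a baseline support-vector
    predictor, a synthetic profile generator, and a command-line workflow
    that reduces building a production classifier to a single call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    kernlab,
    jsonlite,
    methods,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
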