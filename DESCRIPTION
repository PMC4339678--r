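Package: blocknmf
Title: Out-of-Core Non-Negative Matrix Factorization for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-negative matrix factorization (NMF) of gene-expression-like
    matrices by the divergence-based multiplicative update rules, with
    out-of-core blockwise processing of the input under an explicit memory
    budget, an in-process data-parallel mode with replica synchronization,
    and convergence detection via stability of sample-to-factor assignments.
    Includes readers and writers for tab-separated and IEEE little-endian
    binary matrix formats, a planted-structure synthetic data generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
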