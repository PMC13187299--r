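Package: mitostab
Title: mRNA Decay Kinetics and Poly(A) Tail Analysis for Mitotic
    Transcriptome Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify global mRNA stabilization in mitotically
    arrested cells from transcription-shutoff timecourses. Provides
    spike-in/mitochondrial/stable-gene size-factor normalization of count
    matrices, per-gene exponential decay fitting with half-life capping and
    goodness-of-fit filtering, cross-condition stabilization statistics,
    poly(A) tail-length distribution analysis with phased PABPC toeprint
    detection, a per-molecule stochastic deadenylation simulator with
    PABPC-footprint protection, and negative-binomial count simulators that
    generate fully specified synthetic timecourses with known decay truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
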