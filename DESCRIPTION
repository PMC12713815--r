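Package: dreamppl
Title: Perplexity-Based Comparison of Dream-Report and Reference Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how predictable the texts of one corpus are relative to
    another by scoring every document with an autoregressive language model and
    comparing per-document perplexities. Provides self-contained reference
    language models (uniform and additively smoothed n-gram) behind a pluggable
    model contract, strided sliding-window perplexity for long sequences,
    distribution-matched subsampling of word-count distributions, a
    permutation/two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini)
    statistical suite with Holm correction, year-of-collection parsing for
    dream-report metadata, and a synthetic corpus generator with controllable
    source entropy and length laws for end-to-end validation without any
    pretrained weights.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
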