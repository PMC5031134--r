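Package: domarch
Title: Domain-Architecture-Based Pan-Genome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative functional genomics with protein domain
    architectures. Parses per-genome domain-annotation tables
    (InterProScan tab-separated output), derives canonical N-to-C domain
    architecture labels with deterministic tie-breaking for overlapping
    hits, clusters proteins by identical architecture, and computes
    pan-genome statistics: per-cluster persistence, core/pan/singleton
    counts and their ratios, presence/absence principal component
    analysis with outlier flagging, and Heaps' law openness estimation
    from new-cluster accumulation over random genome orderings. Also
    classifies the correspondence between architecture-based and
    sequence-similarity-based clusterings via a directional mismatch
    taxonomy, and ships a synthetic pan-genome generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
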