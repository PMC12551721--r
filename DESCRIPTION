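Package: cgkit
Title: Coordinate-Free CpG Set Analysis for Sparse DNA Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CpG-centric toolkit for interpreting sparse DNA methylomes.
    Provides a coordinate-free whole-genome CpG index, compressed bit-set,
    state and M/U read-count encodings with an indexed multi-sample binary
    container, knowledgebase construction from genomic intervals and gene
    models, hypergeometric CpG-set enrichment testing with domain-wise false
    discovery rate control, normalized pointwise mutual information for set
    co-occurrence, a Poisson genomic proximity test, differential methylation
    calling between sparse profiles, Wilcoxon-AUC cell-type signature
    discovery, and a downsampling harness that quantifies the stability of
    enrichment rankings under CpG sparsity. Seeded synthetic-data generators
    make the full pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
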