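Package: imodn
Title: Prediction and Design of Immunomodulatory Oligodeoxynucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting and designing immunomodulatory
    oligodeoxynucleotides (IMODNs), the short CpG-containing DNA sequences
    that stimulate innate immunity through toll-like receptor 9. Implements
    k-mer (mono- to pentanucleotide) composition features, support vector
    machine classification with threshold-swept sensitivity/specificity/
    accuracy/MCC and rank-based AUC evaluation, discriminative degenerate
    motif mining with exclusivity classes, hybrid motif-weighted scoring,
    position-specific quantitative matrices with minimal-mutation redesign,
    and sequence-design utilities (window scanning, virtual screening of
    single-substitution analogs, reverse-complement palindrome search,
    restriction digest, exact mapping of known oligonucleotides). Includes
    dataset construction from CpG-island fragmentation and a fully synthetic
    benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
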