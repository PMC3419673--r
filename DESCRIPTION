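Package: ampbias
Title: Mock-Community Benchmarking of Amplicon Sequencing Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates 16S rRNA gene mock-community amplicon libraries
    carrying multi-template PCR amplification bias, chimeric PCR
    artifacts, and pyrosequencing-style substitution/indel errors, and
    provides the downstream analysis pipeline: demultiplexing and
    sliding-window quality filtering, k-mer/Needleman-Wunsch alignment to
    a reference seed alignment, reference-based bimera screening,
    average-neighbor OTU clustering, good/spurious OTU classification,
    alpha and beta diversity estimation (Chao1, inverse Simpson,
    non-parametric Shannon, Jaccard, Morisita-Horn), principal
    coordinates analysis, rarefaction-style subsampling, and the bias
    analytics (taxa detection frequency, relative-abundance fold error,
    rank-abundance comparisons, GC-yield correlation) needed to quantify
    how sequencing depth, spurious OTUs and amplification bias distort
    estimates of microbial community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
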