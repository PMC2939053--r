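Package: lrrcensus
Title: Census of Leucine-Rich-Repeat Receptor Architectures Across
    Eukaryotic Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies proteins into leucine-rich-repeat (LRR) receptor
    classes from per-protein domain, transmembrane-helix and
    signal-peptide annotations; corrects topology-prediction and
    gene-model artifacts (signal peptides mispredicted as transmembrane
    helices, spurious N-terminal gene-model extensions); clusters
    LRR-domain subsequences with an in-package Markov clustering (MCL)
    implementation over e-value similarity graphs; and aggregates
    per-species receptor counts into census tables by taxon. A synthetic
    proteome generator with planted ground truth makes every stage
    testable without external genome downloads or domain scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
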