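Package: orthoclust
Title: Taxonomy-Guided Discovery of Orthologous DNA Sequence Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for identifying clusters of orthologous DNA
    sequences from a GenBank-like corpus without relying on gene names.
    Sequences are grouped by all-vs-all similarity search within taxonomic
    work units carved out of an NCBI-taxdump-style taxonomy, clustered by
    single linkage over the filtered hit graph, and merged across units by
    searching the most connected ("seed") sequence of each cluster against
    the others. A post-pipeline toolkit filters clusters by taxonomic
    informativeness, maximum alignment density (MAD), GC content and
    ambiguity, selects per-rank representative sequences, builds
    presence/absence matrices, and exports PhyLoTa-style tables and FASTA
    files. A synthetic-corpus generator evolves gene families along a
    simulated ranked taxonomy so that every pipeline stage can be tested
    offline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
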