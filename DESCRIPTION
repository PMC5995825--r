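Package: micronet
Title: Correlation-Based Co-Occurrence Network Analysis for Microbial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and characterizes microbial co-occurrence networks from
    OTU count tables. OTUs are filtered by per-group prevalence, converted to
    relative abundances, and screened by all-pairs Spearman rank correlation
    with t-approximation p-values and Storey q-values; strong, significant
    correlations define a signed undirected network. The package partitions
    networks with fast greedy modularity optimization, computes standard
    topological indices, compares them against G(n,m) or degree-preserving
    random-network ensembles by Z-tests, quantifies intra- and inter-phylum
    co-occurrence with observed/random (O/R) incidence ratios, classifies
    node roles from within-module (Zi) and among-module (Pi) connectivity,
    and relates module eigengenes to environmental variables. A synthetic
    community generator with planted correlated modules and environmental
    drivers supports end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, igraph, jsonlite, S4Vectors
Suggests: testthat (>= 3.0.0), mclust, withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
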