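Package: coflownet
Title: Co-Occurrence Network Analysis of Riverine Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse bacterial community structure in a river and
    its tributaries from OTU count tables: depth subsampling and
    abundance/prevalence filtering, alpha diversity (richness, Shannon,
    Pielou, Good's coverage), Bray-Curtis beta diversity with NMDS, UPGMA,
    PERMANOVA and Mantel distance-decay tests, signed co-occurrence network
    inference using an ensemble of Pearson, Spearman, Bray-Curtis and
    Kullback-Leibler measures with a renormalized permutation and bootstrap
    (ReBoot-style) null, Simes p-value merging and Benjamini-Hochberg FDR
    control, and network-topology comparison (fast-greedy modules,
    modularity, keystone taxa). A synthetic community generator with
    planted co-occurrence blocks, habitat shifts and spatial distance decay
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    geosphere,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
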