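Package: sigmap
Title: Signature-to-Reference Co-Expression Mapping for Transcriptome Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps differential-expression signatures onto labeled reference
    transcriptome compendia to attribute signature genes to cell states.
    Implements the full chain used to characterize monocyte transcriptomes:
    quantile normalization of the reference compendium, gene-to-gene Pearson
    correlation of signature features across reference samples, average-linkage
    (UPGMA) hierarchical clustering of the correlation matrix with deterministic
    tie-breaking, clipped z-score display matrices, and cluster-to-reference-group
    attribution. Ships a two-group differential-expression scorer (Welch t /
    rank-sum and a pairwise concordance score), hypergeometric gene-set
    over-representation against GMT collections, sample-level statistics (PCA
    explained variance, sample clustering, Mann-Whitney with an exact
    small-sample path, Kruskal-Wallis with Dunn post hoc), a synthetic-data
    generator that plants known co-expression blocks and signatures for
    end-to-end validation, and a YAML-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    cluster,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
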