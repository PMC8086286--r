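Package: spongelnc
Title: Nomination of lncRNA miRNA Sponges from Two-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nominating long non-coding RNAs that act
    as miRNA sponges distinguishing two tumour subtypes (e.g. G-CIMP-low vs
    G-CIMP-high glioma) from bulk RNA-seq counts. Implements counts-per-million
    low-expression filtering, trimmed-mean-of-M-values between-sample
    normalization, a nonparametric differential-expression test that scores
    per-feature M and D statistics against an empirical within-condition noise
    distribution with FDR-controlled selection, and sponge-triplet inference by
    Spearman correlation filtering, shared-miRNA triplet construction,
    first-order Spearman partial correlation and the sensitivity score
    Sz = r_xy - r_xy|z. A synthetic-data generator plants differential
    features, fully mediated sponge triplets and confounder-driven decoys so
    the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
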