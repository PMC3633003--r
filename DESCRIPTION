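Package: goeval
Title: Task-Based Evaluation of Gene Ontology Knowledgebase Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a Gene Ontology structure plus annotation
    corpus recovers known biology through gene-set over-representation
    analysis, and tracks that performance across time-stamped knowledgebase
    snapshots. Parses OBO ontology files and GAF gene-association files,
    propagates annotations over the is_a/part_of closure (true-path rule),
    derives differentially expressed gene lists from two-group expression
    matrices (global-median probe filter, natural-log transform, pooled
    two-sample t-test, Bonferroni correction), runs one-sided Fisher's exact
    enrichment with term-size filtering, and builds term-by-snapshot p-value
    trajectories, including decoupling experiments that freeze either the
    ontology structure or the annotation set to attribute performance changes
    to the other. A synthetic-corpus generator (random DAG ontologies,
    annotation growth series, planted-term expression data) makes every
    pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
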