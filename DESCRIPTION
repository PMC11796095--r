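Package: gotqa
Title: Graph-of-Thoughts Question Answering over Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An agent pipeline that answers natural-language questions over a
    biomedical property graph (genes, drugs, diseases, body parts, pathways).
    A language-model backend proposes and scores candidate strategies, the
    winning strategy is compiled into an XML-defined Graph of Thoughts of
    executable code nodes, and the graph is executed in dependency order
    inside a restricted sandbox with a bounded self-debugging loop. Every
    knowledge-seeking step is grounded in the graph via a Cypher-subset query
    engine, with vector-similarity retrieval as fallback. Ships a
    deterministic scripted backend, a synthetic knowledge-graph generator and
    a six-dataset benchmark (open-ended, true/false, multiple choice; one- and
    two-hop) with self-verifying ground truth and an overlap scorer, so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
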