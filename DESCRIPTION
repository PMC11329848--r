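Package: kgceval
Title: Completion and Quality Evaluation of Typed Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("KG", "Tools", email = "kgtools@example.org", role = c("aut", "cre"))
Description: Tools for completing and evaluating typed biomedical knowledge
    graphs of the syndrome-symptom-pathogenesis-prescription kind, as used in
    traditional Chinese medicine informatics. Implements a three-stage
    completion plan (explicit knowledge via isolated-subgraph re-linking and
    path-ranking link prediction, implicit knowledge via ontology rule
    reasoning with transitivity, symmetry and mutual-exclusivity checks, and
    tacit knowledge via Apriori association-rule mining over medical-record
    transactions with lift-based selection) and a three-dimension quality
    evaluation framework (completeness via network topology, accuracy via
    contradiction counts and centrality agreement with prior knowledge,
    usability via knowledge-graph embeddings scored by mean rank, mean
    reciprocal rank and Hits@N). A synthetic-data generator with a
    planted-truth ledger makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
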