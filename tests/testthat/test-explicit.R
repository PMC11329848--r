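test_that("detect_isolated_subgraphs separates hinted components", {
  gen <- generate_kg(small_gen_config(seed = 7))
  iso <- detect_isolated_subgraphs(gen$kg)
  expect_length(iso, length(gen$ledger$isolated_components))
  hints <- vapply(iso, `[[`, "", "hint")
  expect_setequal(hints, gen$ledger$isolated_hints)

  # fully connected graph -> no isolated subgraphs
  kg <- tiny_kg()
  expect_length(detect_isolated_subgraphs(kg), 0)
})

test_that("link_isolated_subgraphs re-links Fangzheng components only", {
  gen <- generate_kg(small_gen_config(seed = 7))
  links <- link_isolated_subgraphs(gen$kg)
  n_fz <- sum(gen$ledger$isolated_hints == "SubSyndrome")
  expect_equal(nrow(links), n_fz)
  expect_true(all(links$relation == "Treat"))
  expect_true(all(links$provenance == "outlier_completion"))
  # after merging, only the Other-hinted components stay isolated
  kg2 <- merge_triples(gen$kg, links)
  expect_equal(length(connected_components(kg2)),
               1 + sum(gen$ledger$isolated_hints == "Other"))
  # explicit map referencing unknown entities errors
  expect_error(
    link_isolated_subgraphs(gen$kg, c(Ghost = "P001")), "unknown entities")
  # empty map -> no links
  empty <- link_isolated_subgraphs(gen$kg, stats::setNames(character(),
                                                           character()))
  expect_equal(nrow(empty), 0)
})

test_that("path_feature_value is a conforming uniform-walk probability", {
  sch <- tiny_schema()
  # s with two outgoing Manifest edges: uniform split
  kg <- knowledge_graph(
    triples_df(c("S1", "S1"), "Manifest", c("X1", "X2")), sch)
  f1 <- path_feature("Manifest")
  expect_equal(path_feature_value(kg, "S1", f1, "X1"), 0.5)
  # no conforming edge -> 0
  expect_equal(path_feature_value(kg, "X1", f1, "X2"), 0)

  # 2-step value equals exhaustive path-product enumeration
  tr <- triples_df(
    c("S1", "S1", "S2", "X1", "X2", "X3"),
    c("Contain", "Contain", "Contain", "CorrespondTo", "CorrespondTo",
      "CorrespondTo"),
    c("F1", "F2", "F1", "F1", "F1", "F2"))
  kg2 <- knowledge_graph(tr, sch)
  f2 <- path_feature(c("Contain", "CorrespondTo"), c("forward", "inverse"))
  for (tgt in c("X1", "X2", "X3")) {
    expect_equal(path_feature_value(kg2, "S1", f2, tgt),
                 oracle_path_prob(tr, "S1", f2, tgt))
  }
})

test_that("walk probability mass over all targets never exceeds 1", {
  gen <- generate_kg(small_gen_config(seed = 19))
  kg <- gen$kg
  feats <- extract_path_features(kg, "Manifest", 3, n_walks = 10, seed = 2,
                                 max_positives = 30)
  idx <- kgceval:::build_rel_index(kg)
  heads <- unique(kg_triples(kg, "Manifest")$head)[1:5]
  for (f in feats) {
    for (h in heads) {
      mass <- sum(kgceval:::walk_distribution(h, f, idx))
      expect_lte(mass, 1 + 1e-9)
    }
  }
})

test_that("extract_path_features finds the planted evidence path", {
  sch <- tiny_schema()
  # only path from S* to its symptom besides Manifest itself:
  # Contain forward then CorrespondTo inverse
  tr <- triples_df(
    c("S1", "X1", "S1", "S2", "X2", "S2"),
    c("Contain", "CorrespondTo", "Manifest", "Contain", "CorrespondTo",
      "Manifest"),
    c("F1", "F1", "X1", "F2", "F2", "X2"))
  kg <- knowledge_graph(tr, sch)
  feats <- extract_path_features(kg, "Manifest", max_path_length = 2,
                                 n_walks = 200, seed = 3)
  ids <- vapply(feats, kgceval:::feature_id, "")
  expect_true("Contain / CorrespondTo^-1" %in% ids)
  expect_false("Manifest" %in% ids)  # the target relation itself is excluded

  # max_path_length 1 -> only single-relation features
  feats1 <- extract_path_features(kg, "Manifest", max_path_length = 1,
                                  n_walks = 200, seed = 3)
  expect_true(all(lengths(lapply(feats1, `[[`, "relations")) == 1))

  # determinism
  expect_identical(
    extract_path_features(kg, "Manifest", 2, n_walks = 50, seed = 9),
    extract_path_features(kg, "Manifest", 2, n_walks = 50, seed = 9))

  # no instances -> empty with warning
  expect_warning(f0 <- extract_path_features(kg, "Treat", 2, 10, 1),
                 "no instances")
  expect_length(f0, 0)
})

test_that("train_pra separates a separable fixture and is deterministic", {
  sch <- tiny_schema()
  # Manifest holds exactly when the evidence path exists
  tr <- triples_df(
    c("S1", "S2", "S3", "X1", "X2", "X3", "S1", "S2"),
    c("Contain", "Contain", "Contain", "CorrespondTo", "CorrespondTo",
      "CorrespondTo", "Manifest", "Manifest"),
    c("F1", "F2", "F2", "F1", "F2", "F2", "X1", "X2"))
  kg <- knowledge_graph(tr, sch)
  feat <- path_feature(c("Contain", "CorrespondTo"), c("forward", "inverse"))
  m1 <- train_pra(kg, list(feat), "Manifest", negatives_per_positive = 2,
                  seed = 5)
  m2 <- train_pra(kg, list(feat), "Manifest", negatives_per_positive = 2,
                  seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_gt(m1$weights[1], 0)  # evidence path raises the score

  pred <- predict_relations(m1, kg,
                            data.frame(head = "S3", tail = "X2"),
                            support_threshold = 0)
  expect_equal(nrow(pred), 1)  # S3's withheld symptom is proposed
})

test_that("predict_relations enforces support and never re-emits triples", {
  gen <- generate_kg(small_gen_config(seed = 23))
  kg <- gen$kg
  feats <- extract_path_features(kg, "Manifest", 3, n_walks = 30, seed = 4,
                                 max_positives = 80)
  model <- train_pra(kg, feats, "Manifest", seed = 5, max_positives = 80)
  wm <- gen$ledger$withheld_manifest
  cand <- rbind(wm[, c("head", "tail")],
                kg_triples(kg, "Manifest")[1:10, c("head", "tail")],
                data.frame(head = "PF001", tail = "PF002"))  # no features
  pred <- predict_relations(model, kg, cand, support_threshold = 2)
  # existing triples are never re-proposed
  expect_false(any(paste(pred$head, pred$tail) %in%
                   paste(kg_triples(kg, "Manifest")$head[1:10],
                         kg_triples(kg, "Manifest")$tail[1:10])))
  # all-zero-feature pair dropped
  expect_false(any(pred$head == "PF001"))
  expect_true(all(pred$supporting_paths > 2))
  # sorted by (support desc, score desc)
  expect_true(all(diff(pred$supporting_paths) <= 0))

  # ranking equals a hand sort of (support, score)
  ord <- order(-pred$supporting_paths, -pred$score, pred$head, pred$tail)
  expect_identical(ord, seq_len(nrow(pred)))
})

test_that("ontology_filter applies the containment test and is idempotent", {
  sch <- tiny_schema()
  tr <- triples_df(
    c("S1", "X1", "X2", "P1", "S1"),
    c("Contain", "CorrespondTo", "CorrespondTo", "Treat", "Manifest"),
    c("F1", "F1", "F2", "S1", "X3"))
  kg <- knowledge_graph(tr, sch)
  cand <- data.frame(
    head = c("S1", "S1", "P1", "P1", "S1"),
    relation = c("Manifest", "Manifest", "Treat", "Treat", "Manifest"),
    tail = c("X1", "X2", "X1", "X2", "X3"),
    score = 1, supporting_paths = 3L, status = "proposed",
    stringsAsFactors = FALSE)
  out <- ontology_filter(cand, kg)
  # X1's factor F1 is contained by S1 -> accepted; X2's F2 is not -> rejected
  expect_equal(out$status,
               c("ontology_accepted", "ontology_rejected",
                 "ontology_accepted", "ontology_rejected",
                 "ontology_rejected"))  # X3 unmappable -> rejected
  # idempotent and order-independent
  expect_equal(ontology_filter(out, kg)$status, out$status)
  shuffled <- cand[c(3, 1, 5, 2, 4), ]
  out2 <- ontology_filter(shuffled, kg)
  expect_equal(out2$status[order(out2$tail, out2$head)],
               out$status[order(out$tail, out$head)])
})

test_that("gold-standard scoring implements precision/recall/F1", {
  gold <- list(positive = triples_df(c("a", "b", "c"), "R", c("x", "y", "z")),
               negative = triples_df("d", "R", "w"))
  # exact prediction
  r <- evaluate_against_gold(gold$positive, gold)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  # disjoint prediction
  r0 <- evaluate_against_gold(triples_df("q", "R", "q2"), gold)
  expect_equal(c(r0$recall, r0$f1), c(0, 0))
  # mixed: 2 TP, 1 FP-in-negative, 1 FP-unknown
  pred <- rbind(gold$positive[1:2, ], gold$negative,
                triples_df("u", "R", "v"))
  r2 <- evaluate_against_gold(pred, gold)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, round(2 / 3, 4))
  expect_equal(r2$f1, f1_score(0.5, 2 / 3))
  # empty prediction warns
  expect_warning(rw <- evaluate_against_gold(gold$positive[0, ], gold),
                 "undefined")
  expect_equal(rw$precision, 0)
  # overlapping gold sets are rejected
  expect_error(
    evaluate_against_gold(gold$positive,
                          list(positive = gold$positive,
                               negative = gold$positive[1, ])),
    "overlap")
})
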