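# End-to-end orchestration: the fixed three-stage completion order
# explicit (outliers + path reasoning) -> implicit (ontology closure,
# contradiction removal) -> tacit (association rules), each stage operating
# on the cumulative graph, followed by the before/after three-dimension
# evaluation.

#' Pipeline configuration
#'
#' @param stages character subset of `c("explicit", "implicit", "tacit")`;
#'   stages run in this fixed order regardless of how the subset is given.
#' @param pra_target_relations relations to predict in the explicit stage.
#' @param pra_max_path_length,pra_n_walks,pra_max_positives,
#'   pra_negatives_per_positive,pra_support_threshold path-ranking
#'   parameters (see [extract_path_features()], [train_pra()],
#'   [predict_relations()]).
#' @param resolve_policy contradiction policy (see
#'   [resolve_contradictions()]).
#' @param min_support,lift_threshold association-rule parameters.
#' @param evaluate_usability train embedding models on the before/after
#'   graphs? (slowest part; off by default).
#' @param usability_models,usability_dimension,usability_epochs passed to
#'   [usability_report()].
#' @param prior prior-knowledge list for [accuracy_report()].
#' @param seed global seed; stage seeds are derived from it.
#' @return List of class `kgc_run_config`.
#' @export
pipeline_config <- function(stages = c("explicit", "implicit", "tacit"),
                            pra_target_relations = "Manifest",
                            pra_max_path_length = 3, pra_n_walks = 25,
                            pra_max_positives = 200,
                            pra_negatives_per_positive = 1,
                            pra_support_threshold = 2,
                            resolve_policy = "drop_both",
                            min_support = 0.10, lift_threshold = 1,
                            evaluate_usability = FALSE,
                            usability_models = KGE_MODELS,
                            usability_dimension = 32, usability_epochs = 50,
                            prior = list(), seed = 1L) {
  stages <- intersect(c("explicit", "implicit", "tacit"), stages)
  structure(as.list(environment()), class = "kgc_run_config")
}

#' Run the three-stage completion pipeline
#'
#' Stages run in the fixed order explicit -> implicit -> tacit on the
#' cumulative graph. Contradiction removal happens in the implicit stage,
#' before tacit additions, so association-rule triples are never silently
#' deleted. Every added triple carries the provenance of the stage that
#' produced it; original triples are never re-tagged.
#'
#' @param kg the graph to complete.
#' @param config a [pipeline_config()].
#' @param records transactions for the tacit stage (required if enabled).
#' @return List of class `kgc_summary`: `kg_before`, `kg_after`, `added`
#'   (counts per provenance), `removed`, per-stage triple data frames,
#'   `before`/`after` evaluation reports, and `net_delta` bookkeeping.
#' @export
run_pipeline <- function(kg, config = pipeline_config(), records = NULL) {
  stopifnot(inherits(kg, "kg"), inherits(config, "kgc_run_config"))
  before <- kg
  stage_triples <- list()
  removed <- kg$triples[0, c("head", "relation", "tail")]

  if ("explicit" %in% config$stages) {
    outlier_add <- link_isolated_subgraphs(kg)
    stage_triples$outlier <- outlier_add
    if (nrow(outlier_add)) kg <- merge_triples(kg, outlier_add)

    path_add <- list()
    for (rel in config$pra_target_relations) {
      feats <- extract_path_features(
        kg, rel, max_path_length = config$pra_max_path_length,
        n_walks = config$pra_n_walks, seed = config$seed,
        max_positives = config$pra_max_positives)
      if (!length(feats)) next
      model <- train_pra(
        kg, feats, rel,
        negatives_per_positive = config$pra_negatives_per_positive,
        seed = config$seed + 1L, max_positives = config$pra_max_positives)
      cand <- candidate_pairs_for(kg, rel)
      pred <- predict_relations(model, kg, cand,
                                support_threshold =
                                  config$pra_support_threshold)
      pred <- ontology_filter(pred, kg)
      acc <- pred[pred$status == "ontology_accepted", , drop = FALSE]
      if (nrow(acc)) {
        path_add[[rel]] <- data.frame(
          head = acc$head, relation = acc$relation, tail = acc$tail,
          provenance = "path_reasoning", stringsAsFactors = FALSE)
      }
    }
    path_add <- do.call(rbind, path_add)
    stage_triples$path <- path_add
    if (NROW(path_add)) kg <- merge_triples(kg, path_add)
  }

  if ("implicit" %in% config$stages) {
    ont_add <- ontology_closure(kg)
    stage_triples$ontology <- ont_add
    if (nrow(ont_add)) kg <- merge_triples(kg, ont_add)
    pairs <- detect_contradictions(kg)
    if (nrow(pairs)) {
      n_before <- nrow(kg$triples)
      kg2 <- resolve_contradictions(kg, pairs, config$resolve_policy)
      removed <- rbind(removed,
                       kg$triples[!(triple_key(kg$triples) %in%
                                    triple_key(kg2$triples)),
                                  c("head", "relation", "tail")])
      kg <- kg2
    }
  }

  if ("tacit" %in% config$stages) {
    if (is.null(records)) stop("tacit stage enabled but no records supplied")
    freq <- apriori_frequent_itemsets(records, config$min_support)
    rules <- derive_rules(freq,
                          antecedent_items =
                            kg_entities_of_type(kg, c("Syndrome",
                                                      "SubSyndrome")),
                          consequent_items =
                            kg_entities_of_type(kg, "Symptom"))
    assoc_add <- select_and_convert(rules, config$lift_threshold,
                                    "Manifest", kg)
    stage_triples$association <- assoc_add
    stage_triples$rules <- rules
    if (nrow(assoc_add)) kg <- merge_triples(kg, assoc_add)
  }

  added <- vapply(stage_triples[c("outlier", "path", "ontology",
                                  "association")], NROW, 0L)
  eval_side <- function(g) {
    side <- list(completeness = completeness_report(g),
                 accuracy = accuracy_report(g, config$prior))
    if (config$evaluate_usability) {
      side$usability <- usability_report(
        g, models = config$usability_models,
        dimension = config$usability_dimension,
        epochs = config$usability_epochs, seed = config$seed)
    }
    side
  }
  structure(list(
    kg_before = before, kg_after = kg,
    added = added, removed = nrow(removed),
    removed_triples = removed, stage_triples = stage_triples,
    before = eval_side(before), after = eval_side(kg),
    net_delta = nrow(kg$triples) - nrow(before$triples),
    stage_order = config$stages), class = "kgc_summary")
}

# all type-compatible (head, tail) pairs for a target relation, minus pairs
# already connected by it
candidate_pairs_for <- function(kg, relation) {
  spec <- relation_spec(kg, relation)
  heads <- if (spec$domain == "any") {
    unique(kg_triples(kg, relation)$head)
  } else kg_entities_of_type(kg, spec$domain)
  tails <- if (spec$range == "any") {
    unique(kg_triples(kg, relation)$tail)
  } else kg_entities_of_type(kg, spec$range)
  expand.grid(head = heads, tail = tails, stringsAsFactors = FALSE)
}

#' @export
print.kgc_summary <- function(x, ...) {
  cat("<kgc_summary> stages:", paste(x$stage_order, collapse = " -> "), "\n")
  cat("  added:", paste(names(x$added), x$added, sep = "=", collapse = " "),
      "| removed:", x$removed, "| net triple delta:", x$net_delta, "\n")
  cat("  triples:", nrow(x$kg_before$triples), "->",
      nrow(x$kg_after$triples), "; nodes:", nrow(x$kg_before$entities),
      "->", nrow(x$kg_after$entities), "\n")
  invisible(x)
}

#' Tabulate before/after deltas of a completed run
#'
#' @param before,after evaluation sides (the `before` / `after` elements of
#'   a [run_pipeline()] summary, each with `completeness`, `accuracy` and
#'   optionally `usability`).
#' @return List of class `kgc_delta`: node/edge/density/contradiction
#'   deltas, prior-proportion deltas, and per-model MR/MRR/Hits deltas when
#'   usability was evaluated.
#' @export
compare_reports <- function(before, after) {
  cb <- before$completeness; ca <- after$completeness
  out <- list(
    node_delta = ca$n_nodes - cb$n_nodes,
    edge_delta = ca$n_edges - cb$n_edges,
    density_delta = ca$density - cb$density,
    k_avg_delta = ca$k_avg - cb$k_avg,
    contradiction_delta = after$accuracy$contradiction_count -
      before$accuracy$contradiction_count)
  if (!is.null(before$accuracy$top_closeness)) {
    out$closeness_proportion_delta <-
      after$accuracy$top_closeness$proportion -
      before$accuracy$top_closeness$proportion
  }
  if (!is.null(before$accuracy$kcore)) {
    out$kcore_proportion_delta <- after$accuracy$kcore$proportion -
      before$accuracy$kcore$proportion
  }
  if (!is.null(before$usability)) {
    out$usability_delta <- lapply(names(before$usability), function(m) {
      b <- before$usability[[m]]; a <- after$usability[[m]]
      list(model = m, mr = a$mr - b$mr, mrr = a$mrr - b$mrr,
           hits1 = a$hits1 - b$hits1, hits3 = a$hits3 - b$hits3,
           hits10 = a$hits10 - b$hits10)
    })
  }
  structure(out, class = "kgc_delta")
}

#' @export
print.kgc_delta <- function(x, ...) {
  cat("<kgc_delta> nodes ", sprintf("%+d", x$node_delta), ", edges ",
      sprintf("%+d", x$edge_delta), ", density ",
      sprintf("%+.4f", x$density_delta), ", contradictions ",
      sprintf("%+d", x$contradiction_delta), "\n", sep = "")
  invisible(x)
}
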