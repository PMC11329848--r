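# Explicit ("path"-level) completion: isolated-subgraph detection and
# re-linking, and path-ranking link prediction (random-walk relation-path
# features feeding a logistic linear classifier), with an ontology
# consistency filter and precision/recall/F1 scoring against a gold standard.

#' Detect isolated subgraphs
#'
#' Returns every connected component except the largest one. A component is
#' hinted `SubSyndrome` (a Fangzheng component, completable by re-linking to
#' its prescription) if it contains at least one SubSyndrome-typed entity,
#' otherwise `Other` (left uncompleted). Ties for the largest component are
#' broken by the lexicographically smallest member id.
#'
#' @param kg a `kg`.
#' @return List of `list(entities = <character>, hint = <"SubSyndrome"|"Other">)`.
#' @export
detect_isolated_subgraphs <- function(kg) {
  comps <- connected_components(kg)
  if (length(comps) <= 1) return(list())
  lapply(comps[-1], function(ids) {
    types <- kg$entities$type[match(ids, kg$entities$id)]
    list(entities = ids,
         hint = if ("SubSyndrome" %in% types) "SubSyndrome" else "Other")
  })
}

#' Re-link isolated Fangzheng components
#'
#' Emits `(Prescription, Treat, SubSyndrome)` triples with provenance
#' `outlier_completion` for SubSyndrome entities inside isolated components.
#' With `link_map = NULL` the default name-pattern resolver is used: a
#' subsyndrome whose id is `"<x> Syndrome"` links to the prescription with id
#' `<x>`, when that prescription exists. Components hinted `Other` are left
#' untouched.
#'
#' @param kg a `kg`.
#' @param link_map named character vector, SubSyndrome id -> Prescription id,
#'   or `NULL` for the name-pattern resolver.
#' @return Data frame of new Treat triples (possibly 0 rows).
#' @export
link_isolated_subgraphs <- function(kg, link_map = NULL) {
  iso <- detect_isolated_subgraphs(kg)
  subs <- unlist(lapply(iso, function(co)
    if (co$hint == "SubSyndrome")
      co$entities[kg$entities$type[match(co$entities, kg$entities$id)] ==
                  "SubSyndrome"]))
  subs <- unique(subs)
  empty <- data.frame(head = character(), relation = character(),
                      tail = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (is.null(link_map)) {
    cand <- sub(" Syndrome$", "", subs)
    ok <- grepl(" Syndrome$", subs) & cand %in% kg$entities$id
    link_map <- stats::setNames(cand[ok], subs[ok])
  } else {
    bad <- setdiff(c(names(link_map), unname(link_map)), kg$entities$id)
    if (length(bad)) {
      stop("lookup error: link_map references unknown entities: ",
           paste(bad, collapse = ", "))
    }
    link_map <- link_map[names(link_map) %in% subs]
  }
  if (!length(link_map)) return(empty)
  data.frame(head = unname(link_map), relation = "Treat",
             tail = names(link_map), provenance = "outlier_completion",
             stringsAsFactors = FALSE)
}

# adjacency index: for each relation, out[[node]] and in[[node]] neighbor
# vectors; plus a flat per-node step table for random walks
build_rel_index <- function(kg) {
  tr <- kg$triples
  idx <- new.env(parent = emptyenv())
  idx$out <- lapply(split(tr[c("head", "tail")], tr$relation),
                    function(d) split(d$tail, d$head))
  idx$in_ <- lapply(split(tr[c("head", "tail")], tr$relation),
                    function(d) split(d$head, d$tail))
  # flat walk table: node -> data.frame(nbr, rel, dir)
  fl <- rbind(
    data.frame(from = tr$head, nbr = tr$tail, rel = tr$relation,
               dir = "forward", stringsAsFactors = FALSE),
    data.frame(from = tr$tail, nbr = tr$head, rel = tr$relation,
               dir = "inverse", stringsAsFactors = FALSE))
  idx$walk <- split(fl[c("nbr", "rel", "dir")], fl$from)
  idx
}

#' Path feature: a typed relation sequence
#'
#' @param relations character vector of relation names.
#' @param directions matching vector of `"forward"` / `"inverse"` (default
#'   all forward).
#' @return An object of class `kg_path_feature`.
#' @export
path_feature <- function(relations, directions = rep("forward",
                                                     length(relations))) {
  stopifnot(length(relations) >= 1, length(directions) == length(relations),
            all(directions %in% c("forward", "inverse")))
  structure(list(relations = relations, directions = directions),
            class = "kg_path_feature")
}

#' @export
print.kg_path_feature <- function(x, ...) {
  cat(feature_id(x), "\n")
  invisible(x)
}

feature_id <- function(f) {
  paste(paste0(f$relations, ifelse(f$directions == "inverse", "^-1", "")),
        collapse = " / ")
}

# distribution of a relation-constrained uniform random walk started at
# `source`, after following every step of `feature`; named vector over the
# nodes holding nonzero mass
walk_distribution <- function(source, feature, index) {
  dist <- stats::setNames(1, source)
  for (s in seq_along(feature$relations)) {
    adj <- if (feature$directions[s] == "forward")
      index$out[[feature$relations[s]]] else index$in_[[feature$relations[s]]]
    if (is.null(adj)) return(stats::setNames(numeric(0), character(0)))
    nxt <- list()
    for (u in names(dist)) {
      nb <- adj[[u]]
      if (length(nb)) {
        nxt[[length(nxt) + 1]] <- stats::setNames(
          rep(dist[[u]] / length(nb), length(nb)), nb)
      }
    }
    if (!length(nxt)) return(stats::setNames(numeric(0), character(0)))
    v <- unlist(nxt)
    dist <- vapply(split(unname(v), names(v)), sum, 0)
  }
  dist
}

#' Random-walk probability of reaching a target along a relation path
#'
#' The walker starts at `source`; at each step it moves along one uniformly
#' chosen edge with the required relation and direction. The returned value
#' is the total probability over all conforming paths of arriving at
#' `target`; 0 when no conforming path exists. Summed over all targets the
#' value is at most 1 (mass is lost when the walker has no conforming edge).
#'
#' @param kg a `kg`.
#' @param source,target entity ids.
#' @param feature a [path_feature()].
#' @return Probability in `[0, 1]`.
#' @export
path_feature_value <- function(kg, source, feature, target) {
  stopifnot(inherits(feature, "kg_path_feature"))
  index <- build_rel_index(kg)
  d <- walk_distribution(source, feature, index)
  if (target %in% names(d)) unname(d[[target]]) else 0
}

#' Extract relation-path features by random walks
#'
#' Runs bounded uniform random walks (over all relations, both directions)
#' from the heads of known `target_relation` triples and keeps every relation
#' sequence that ends at the triple's known tail within `max_path_length`
#' steps. Sequences are deduplicated and the length-1 sequence equal to the
#' target relation itself is excluded. Deterministic given `seed`.
#'
#' @param kg a `kg`.
#' @param target_relation relation whose instances seed the walks.
#' @param max_path_length maximum walk length (default 3).
#' @param n_walks walks per seed triple.
#' @param seed integer seed.
#' @param max_positives cap on the number of seed triples used (sampled);
#'   `Inf` uses all.
#' @return List of [path_feature()] objects (possibly empty, with a warning
#'   when the relation has no instances).
#' @export
extract_path_features <- function(kg, target_relation, max_path_length = 3,
                                  n_walks = 1000, seed = 1L,
                                  max_positives = Inf) {
  stopifnot(max_path_length >= 1, n_walks >= 1)
  pos <- kg_triples(kg, target_relation)
  if (!nrow(pos)) {
    warning("no instances of target relation ", target_relation)
    return(list())
  }
  index <- build_rel_index(kg)
  with_seed(seed, {
    if (nrow(pos) > max_positives) {
      pos <- pos[sample(nrow(pos), max_positives), ]
    }
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(pos))) {
      h <- pos$head[i]; t <- pos$tail[i]
      for (w in seq_len(n_walks)) {
        node <- h
        rels <- character(max_path_length)
        dirs <- character(max_path_length)
        for (s in seq_len(max_path_length)) {
          steps <- index$walk[[node]]
          if (is.null(steps) || !nrow(steps)) break
          j <- sample.int(nrow(steps), 1)
          node <- steps$nbr[j]
          rels[s] <- steps$rel[j]
          dirs[s] <- steps$dir[j]
          if (node == t) {
            if (!(s == 1 && rels[1] == target_relation &&
                  dirs[1] == "forward")) {
              key <- paste(rels[1:s], dirs[1:s], collapse = "|")
              if (is.null(seen[[key]])) {
                seen[[key]] <- path_feature(rels[1:s], dirs[1:s])
              }
            }
            break
          }
        }
      }
    }
    feats <- as.list(seen)
    if (!length(feats)) return(list())
    unname(feats[order(names(feats))])
  })
}

# feature-value matrix for (head, tail) pairs: one walk distribution per
# (distinct head, feature), values read off at the tails
feature_matrix <- function(kg, pairs, features, index = build_rel_index(kg)) {
  X <- matrix(0, nrow(pairs), length(features))
  for (h in unique(pairs$head)) {
    rows <- which(pairs$head == h)
    for (j in seq_along(features)) {
      d <- walk_distribution(h, features[[j]], index)
      hit <- match(pairs$tail[rows], names(d))
      X[rows[!is.na(hit)], j] <- d[hit[!is.na(hit)]]
    }
  }
  colnames(X) <- vapply(features, feature_id, "")
  X
}

#' Train a path-ranking classifier
#'
#' Positives are the existing `target_relation` triples; negatives are
#' tail-corrupted copies (tails drawn uniformly from entities with the same
#' type as the true tail, `negatives_per_positive` each, seeded, excluding
#' corruptions that are themselves true triples). A logistic-loss linear
#' classifier is fitted on the random-walk feature values; the score of a
#' pair is the linear predictor `intercept + sum_j P(s -> t; pi_j) * theta_j`.
#'
#' @param kg a `kg`.
#' @param features list of [path_feature()] objects.
#' @param target_relation relation to model.
#' @param negatives_per_positive corrupted tails per positive (default 1).
#' @param seed integer seed.
#' @param max_positives cap on positives used for fitting (sampled).
#' @return Object of class `kg_pra_model` with `features`, `weights`,
#'   `intercept`, `target_relation`.
#' @export
train_pra <- function(kg, features, target_relation,
                      negatives_per_positive = 1, seed = 1L,
                      max_positives = Inf) {
  stopifnot(length(features) >= 1)
  pos <- kg_triples(kg, target_relation)
  if (!nrow(pos)) stop("no positive triples for ", target_relation)
  known <- triple_key(pos)
  index <- build_rel_index(kg)
  with_seed(seed, {
    if (nrow(pos) > max_positives) pos <- pos[sample(nrow(pos), max_positives), ]
    negs <- list()
    for (i in seq_len(nrow(pos))) {
      ty <- kg$entities$type[match(pos$tail[i], kg$entities$id)]
      pool <- setdiff(kg_entities_of_type(kg, ty), pos$tail[i])
      if (!length(pool)) next
      t_new <- sample(pool, min(negatives_per_positive, length(pool)))
      cand <- data.frame(head = pos$head[i], relation = target_relation,
                         tail = t_new, stringsAsFactors = FALSE)
      cand <- cand[!(triple_key(cand) %in% known), , drop = FALSE]
      if (nrow(cand)) negs[[length(negs) + 1]] <- cand
    }
    neg <- do.call(rbind, negs)
    pairs <- rbind(pos[c("head", "tail")], neg[c("head", "tail")])
    y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
    X <- feature_matrix(kg, pairs, features, index)
    if (all(apply(X, 2, function(col) length(unique(col))) == 1)) {
      warning("all feature columns are constant; model reduces to base rate")
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    structure(list(target_relation = target_relation, features = features,
                   weights = fit$coefficients[-1],
                   intercept = fit$coefficients[1]),
              class = "kg_pra_model")
  })
}

#' @export
print.kg_pra_model <- function(x, ...) {
  cat("<kg_pra_model> target:", x$target_relation, "|",
      length(x$features), "path features\n")
  w <- x$weights
  names(w) <- vapply(x$features, feature_id, "")
  print(round(w, 4))
  invisible(x)
}

#' Score candidate pairs and keep well-supported ones
#'
#' Scores every candidate `(head, tail)` pair not already connected by the
#' model's target relation. `supporting_paths` counts the features with a
#' nonzero random-walk value; only candidates with more than
#' `support_threshold` supporting paths are kept (default threshold 2, i.e.
#' at least 3 supporting paths), flagged `proposed`. Results are sorted by
#' `(supporting_paths, score)` descending.
#'
#' @param model a `kg_pra_model`.
#' @param kg the graph the model was trained on.
#' @param candidate_pairs data frame with columns `head`, `tail`.
#' @param support_threshold keep candidates with strictly more supporting
#'   paths than this.
#' @return Data frame of candidates: `head`, `relation`, `tail`, `score`,
#'   `supporting_paths`, `status`.
#' @export
predict_relations <- function(model, kg, candidate_pairs,
                              support_threshold = 2) {
  stopifnot(inherits(model, "kg_pra_model"))
  pairs <- as.data.frame(candidate_pairs, stringsAsFactors = FALSE)
  cand <- data.frame(head = pairs$head, relation = model$target_relation,
                     tail = pairs$tail, stringsAsFactors = FALSE)
  keep <- !(triple_key(cand) %in% triple_key(kg$triples))
  pairs <- pairs[keep, , drop = FALSE]
  empty <- data.frame(head = character(), relation = character(),
                      tail = character(), score = numeric(),
                      supporting_paths = integer(), status = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  X <- feature_matrix(kg, pairs, model$features)
  support <- rowSums(X > 0)
  score <- drop(X %*% model$weights) + model$intercept
  out <- data.frame(head = pairs$head, relation = model$target_relation,
                    tail = pairs$tail, score = score,
                    supporting_paths = as.integer(support),
                    status = "proposed", stringsAsFactors = FALSE)
  out <- out[out$supporting_paths > support_threshold, , drop = FALSE]
  out <- out[order(-out$supporting_paths, -out$score, out$head, out$tail), ]
  rownames(out) <- NULL
  out
}

#' Ontology consistency filter for predicted triples
#'
#' A `(Syndrome, Manifest, Symptom)` candidate is accepted iff the symptom
#' maps (via `CorrespondTo`) to at least one pathogenesis factor and every
#' such factor is contained by the syndrome (via `Contain`). A
#' `(Prescription, Treat, Symptom)` candidate is first mapped to the
#' prescription's curable syndromes (its `Treat` tails of type Syndrome);
#' it is accepted iff the same containment test passes for at least one of
#' them. All other candidates, and candidates whose symptom has no
#' `CorrespondTo` mapping, are rejected. Idempotent and order-independent.
#'
#' @param candidates data frame as returned by [predict_relations()].
#' @param kg a `kg` containing `CorrespondTo`, `Treat` and `Contain` triples.
#' @return `candidates` with `status` set to `ontology_accepted` /
#'   `ontology_rejected`.
#' @export
ontology_filter <- function(candidates, kg) {
  if (!NROW(candidates)) return(candidates)
  corr <- kg_triples(kg, "CorrespondTo")
  contain <- kg_triples(kg, "Contain")
  treat <- kg_triples(kg, "Treat")
  syn_ids <- kg_entities_of_type(kg, c("Syndrome", "SubSyndrome"))
  factors_of <- split(corr$tail, corr$head)
  contain_key <- paste(contain$head, contain$tail)
  curable <- split(treat$tail[treat$tail %in% syn_ids],
                   treat$head[treat$tail %in% syn_ids])
  ety <- stats::setNames(kg$entities$type, kg$entities$id)

  contains_all <- function(s, pf) {
    length(pf) > 0 && all(paste(s, pf) %in% contain_key)
  }
  status <- vapply(seq_len(nrow(candidates)), function(i) {
    rel <- candidates$relation[i]
    h <- candidates$head[i]; t <- candidates$tail[i]
    pf <- factors_of[[t]]
    if (is.null(pf) || !length(pf)) return("ontology_rejected")  # unmappable
    ok <- if (rel == "Manifest" && ety[h] %in% c("Syndrome", "SubSyndrome")) {
      contains_all(h, pf)
    } else if (rel == "Treat" && ety[h] == "Prescription") {
      any(vapply(curable[[h]], contains_all, TRUE, pf = pf))
    } else FALSE
    if (ok) "ontology_accepted" else "ontology_rejected"
  }, "")
  candidates$status <- status
  candidates
}

#' Read a gold-standard triple file
#'
#' TSV with columns `head`, `relation`, `tail`, `label`; `label` is
#' `positive` or `negative` (expert annotation). No header.
#'
#' @param path file path.
#' @return List with data frames `positive` and `negative`.
#' @export
read_gold <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("head", "relation", "tail", "label"),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  bad <- setdiff(unique(d$label), c("positive", "negative"))
  if (length(bad)) stop("unknown gold label(s): ", paste(bad, collapse = ", "))
  list(positive = d[d$label == "positive", 1:3],
       negative = d[d$label == "negative", 1:3])
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2PR/(P+R)`, with `F1 = 0` when `P + R = 0`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param digits rounding applied to the result (default 4).
#' @return The F1 value.
#' @export
f1_score <- function(precision, recall, digits = 4) {
  if (precision + recall == 0) return(0)
  round(2 * precision * recall / (precision + recall), digits)
}

#' Precision, recall and F1 against a gold standard
#'
#' `TP` are predictions in the positive set; `FP` are predictions in the
#' negative set or outside both sets (closed-world for predictions); `FN`
#' are positives not predicted. `F1 = 2PR/(P+R)`. Undefined precision
#' (no predictions) is reported as 0 with a warning; `P + R = 0` gives
#' `F1 = 0`. All values are rounded to 4 decimals.
#'
#' @param predicted data frame of predicted triples (`head`, `relation`,
#'   `tail`).
#' @param gold list with data-frame elements `positive` and `negative`
#'   (disjoint).
#' @return List with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
evaluate_against_gold <- function(predicted, gold) {
  stopifnot(NROW(gold$positive) > 0)
  pk <- if (NROW(predicted)) triple_key(predicted) else character()
  pos <- triple_key(gold$positive)
  neg <- if (NROW(gold$negative)) triple_key(gold$negative) else character()
  if (length(intersect(pos, neg))) {
    stop("gold standard positive and negative sets overlap")
  }
  tp <- sum(pk %in% pos)
  fp <- sum(!(pk %in% pos))
  fn <- sum(!(pos %in% pk))
  if (tp + fp == 0) {
    warning("no predictions: precision undefined, reported as 0")
    p <- 0
  } else p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = round(p, 4), recall = round(r, 4), f1 = round(f1, 4),
       tp = tp, fp = fp, fn = fn)
}
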