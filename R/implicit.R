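# Ontology-level ("implicit") completion: transitive and symmetric closure
# of flagged relations, and contradiction detection/resolution via
# mutual-exclusivity pairs.

relation_spec <- function(kg, relation) {
  i <- match(relation, kg$schema$relations$name)
  if (is.na(i)) stop("unknown relation: ", relation)
  kg$schema$relations[i, ]
}

#' Missing transitive-closure triples of a relation
#'
#' Computes the transitive closure of `relation` and returns exactly the
#' triples in the closure that are absent from the graph, with provenance
#' `ontology_reasoning`. Terminates on cyclic inputs; self-loops produced by
#' cycles are discarded. Idempotent: applied to an already-closed relation it
#' returns nothing.
#'
#' @param kg a `kg`.
#' @param relation a relation flagged `transitive` in the schema.
#' @return Data frame of new triples (possibly 0 rows).
#' @export
transitive_closure <- function(kg, relation) {
  spec <- relation_spec(kg, relation)
  if (!spec$transitive) {
    stop("usage error: relation not flagged transitive: ", relation)
  }
  tr <- kg_triples(kg, relation)
  if (!nrow(tr)) return(tr[0, ])
  nodes <- sort(unique(c(tr$head, tr$tail)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(match(tr$head, nodes), match(tr$tail, nodes))] <- TRUE
  # boolean matrix powering by repeated squaring of the reachability step
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  idx <- which(reach & !adj, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]  # drop cycle self-loops
  out <- data.frame(head = nodes[idx[, 1]],
                    relation = rep(relation, nrow(idx)),
                    tail = nodes[idx[, 2]],
                    provenance = rep("ontology_reasoning", nrow(idx)),
                    stringsAsFactors = FALSE)
  out[order(out$head, out$tail), ]
}

#' Missing symmetric-closure triples of a relation
#'
#' For every triple `(h, relation, t)` lacking its reverse, returns
#' `(t, relation, h)` with provenance `ontology_reasoning`. Idempotent.
#'
#' @param kg a `kg`.
#' @param relation a relation flagged `symmetric` in the schema.
#' @return Data frame of new triples (possibly 0 rows).
#' @export
symmetric_closure <- function(kg, relation) {
  spec <- relation_spec(kg, relation)
  if (!spec$symmetric) {
    stop("usage error: relation not flagged symmetric: ", relation)
  }
  tr <- kg_triples(kg, relation)
  if (!nrow(tr)) return(tr[0, ])
  have <- paste(tr$head, tr$tail)
  need <- !(paste(tr$tail, tr$head) %in% have) & tr$head != tr$tail
  out <- data.frame(head = tr$tail[need],
                    relation = rep(relation, sum(need)),
                    tail = tr$head[need],
                    provenance = rep("ontology_reasoning", sum(need)),
                    stringsAsFactors = FALSE)
  out[order(out$head, out$tail), ]
}

#' All missing ontology-closure triples
#'
#' Convenience wrapper: union of [transitive_closure()] over all transitive
#' relations and [symmetric_closure()] over all symmetric relations.
#'
#' @param kg a `kg`.
#' @return Data frame of new triples.
#' @export
ontology_closure <- function(kg) {
  rel <- kg$schema$relations
  parts <- c(lapply(rel$name[rel$transitive], transitive_closure, kg = kg),
             lapply(rel$name[rel$symmetric], symmetric_closure, kg = kg))
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- kg$triples[0, ]
  }
  rownames(out) <- NULL
  out
}

#' Detect mutually exclusive triple pairs
#'
#' Enumerates every `(head, tail)` pair that carries both relations of any
#' mutual-exclusivity pair declared in the schema (e.g. a prescription that
#' both treats and is contraindicated for the same syndrome).
#'
#' @param kg a `kg`.
#' @return Data frame with columns `head`, `tail`, `relation_a`,
#'   `relation_b` (relation_a < relation_b lexicographically), ordered by
#'   `(head, tail)`.
#' @export
detect_contradictions <- function(kg) {
  ex <- exclusivity_pairs(kg$schema)
  empty <- data.frame(head = character(), tail = character(),
                      relation_a = character(), relation_b = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ex)) return(empty)
  out <- empty
  for (i in seq_len(nrow(ex))) {
    ta <- kg_triples(kg, ex$relation_a[i])
    tb <- kg_triples(kg, ex$relation_b[i])
    hit <- paste(ta$head, ta$tail) %in% paste(tb$head, tb$tail)
    if (any(hit)) {
      out <- rbind(out, data.frame(head = ta$head[hit], tail = ta$tail[hit],
                                   relation_a = ex$relation_a[i],
                                   relation_b = ex$relation_b[i],
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$head, out$tail), ]
  rownames(out) <- NULL
  out
}

#' Resolve contradictions
#'
#' Removes triples of contradiction pairs according to `keep_policy`:
#' `"drop_both"` removes both triples of each pair; `"keep_first_relation"`
#' keeps the `relation_a` triple and removes the `relation_b` triple;
#' `"decisions"` consults `decisions`, a data frame with columns `head`,
#' `tail`, `keep` (a relation name) — pairs without an entry are reported
#' and left untouched.
#'
#' @param kg a `kg`.
#' @param pairs output of [detect_contradictions()] on `kg`.
#' @param keep_policy one of `"drop_both"`, `"keep_first_relation"`,
#'   `"decisions"`.
#' @param decisions decisions data frame (only for `keep_policy =
#'   "decisions"`).
#' @return A new `kg` with the selected triples removed.
#' @export
resolve_contradictions <- function(kg, pairs,
                                   keep_policy = c("drop_both",
                                                   "keep_first_relation",
                                                   "decisions"),
                                   decisions = NULL) {
  keep_policy <- match.arg(keep_policy)
  if (!NROW(pairs)) return(kg)
  rm_list <- list()
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$head[i]; t <- pairs$tail[i]
    ra <- pairs$relation_a[i]; rb <- pairs$relation_b[i]
    drop_rel <- switch(keep_policy,
      drop_both = c(ra, rb),
      keep_first_relation = rb,
      decisions = {
        j <- which(decisions$head == h & decisions$tail == t)
        if (!length(j)) {
          warning("unresolved contradiction (", h, ", ", t,
                  "): no decision entry; left unchanged")
          NULL
        } else {
          setdiff(c(ra, rb), decisions$keep[j[1]])
        }
      })
    if (length(drop_rel)) {
      rm_list[[length(rm_list) + 1]] <- data.frame(
        head = h, relation = drop_rel, tail = t, stringsAsFactors = FALSE)
    }
  }
  if (!length(rm_list)) return(kg)
  merge_triples(kg, removals = do.call(rbind, rm_list))
}
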