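# Typed knowledge graph: entities + provenance-tagged triples + schema.
# Triples are stored directed (head -> tail); all topology metrics use the
# undirected view (see kg_igraph).

PROVENANCE_TAGS <- c("original", "outlier_completion", "path_reasoning",
                     "ontology_reasoning", "association_rule")

#' Construct a knowledge graph
#'
#' Builds a validated typed knowledge graph from a triple table and a schema.
#' Entities are auto-registered from triple endpoints; their types come from
#' the schema's `entity_type_map` (unmapped ids get type `"Other"`).
#' Duplicate `(head, relation, tail)` rows are deduplicated, keeping the first
#' occurrence's provenance.
#'
#' @param triples data frame with character columns `head`, `relation`,
#'   `tail` and optionally `provenance` (default `"original"`).
#' @param schema a [kg_schema()].
#' @param extra_entities optional character vector of entity ids to register
#'   even if they occur in no triple (isolated nodes).
#' @return An object of class `kg` with fields `triples` (data frame),
#'   `entities` (data frame with `id`, `label`, `type`), and `schema`.
#' @export
knowledge_graph <- function(triples, schema, extra_entities = character()) {
  stopifnot(inherits(schema, "kg_schema"))
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (nrow(triples) == 0) {
    triples <- data.frame(head = character(), relation = character(),
                          tail = character(), provenance = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  if (is.null(triples$provenance)) triples$provenance <- "original"
  triples$provenance[is.na(triples$provenance) | triples$provenance == ""] <-
    "original"
  bad_prov <- setdiff(unique(triples$provenance), PROVENANCE_TAGS)
  if (length(bad_prov)) {
    stop("unknown provenance tag(s): ", paste(bad_prov, collapse = ", "))
  }
  triples <- triples[, c("head", "relation", "tail", "provenance")]
  for (cl in names(triples)) triples[[cl]] <- as.character(triples[[cl]])
  triples <- triples[!duplicated(triples[, c("head", "relation", "tail")]), ,
                     drop = FALSE]
  rownames(triples) <- NULL

  undeclared <- setdiff(unique(triples$relation), schema$relations$name)
  if (length(undeclared)) {
    stop("schema violation: undeclared relation(s): ",
         paste(undeclared, collapse = ", "))
  }

  ids <- unique(c(triples$head, triples$tail, extra_entities))
  entities <- data.frame(id = ids, label = ids,
                         type = entity_type_of(schema, ids),
                         stringsAsFactors = FALSE)
  kg <- structure(list(triples = triples, entities = entities,
                       schema = schema), class = "kg")
  check_domain_range(kg)
  kg
}

check_domain_range <- function(kg) {
  tr <- kg$triples
  if (!nrow(tr)) return(invisible(TRUE))
  rel <- kg$schema$relations
  ht <- entity_type_of(kg$schema, tr$head)
  tt <- entity_type_of(kg$schema, tr$tail)
  i <- match(tr$relation, rel$name)
  bad <- (rel$domain[i] != "any" & rel$domain[i] != ht) |
         (rel$range[i] != "any" & rel$range[i] != tt)
  if (any(bad)) {
    off <- utils::head(sprintf("(%s, %s, %s)", tr$head[bad], tr$relation[bad],
                               tr$tail[bad]), 10)
    stop("schema violation: domain/range mismatch for ", sum(bad),
         " triple(s): ", paste(off, collapse = " "))
  }
  invisible(TRUE)
}

#' @export
print.kg <- function(x, ...) {
  cat("<kg> ", nrow(x$entities), " entities, ", nrow(x$triples),
      " triples\n", sep = "")
  tb <- table(x$triples$provenance)
  cat("  provenance:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Load a knowledge graph from a triple TSV and a schema JSON
#'
#' The triple file is UTF-8 TSV, one triple per line:
#' `head \t relation \t tail [\t provenance]` with no header. Provenance
#' defaults to `"original"`. Entities are auto-registered; types come from the
#' schema's id-to-type map.
#'
#' @param triple_path path to the triple TSV.
#' @param schema_path path to the schema JSON (see [read_schema()]), or an
#'   already-parsed `kg_schema`.
#' @return A validated `kg`.
#' @export
load_triples <- function(triple_path, schema_path) {
  schema <- if (inherits(schema_path, "kg_schema")) schema_path
            else read_schema(schema_path)
  lines <- readLines(triple_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(knowledge_graph(data.frame(), schema))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 3)
  if (length(bad)) {
    stop("parse error in ", triple_path, ": line ", bad[1],
         " has ", nfield[bad[1]], " field(s), expected >= 3")
  }
  triples <- data.frame(
    head = vapply(parts, `[[`, "", 1),
    relation = vapply(parts, `[[`, "", 2),
    tail = vapply(parts, `[[`, "", 3),
    provenance = vapply(parts, function(p)
      if (length(p) >= 4 && nzchar(p[4])) p[4] else "original", ""),
    stringsAsFactors = FALSE)
  knowledge_graph(triples, schema)
}

#' Save a knowledge graph's triples to TSV
#'
#' Writes `head \t relation \t tail \t provenance`, no header, UTF-8, so that
#' `load_triples(save_triples(kg, path), schema)` reproduces the triple set.
#'
#' @param kg a `kg`.
#' @param path output path.
#' @return The number of triples written, invisibly.
#' @export
save_triples <- function(kg, path) {
  stopifnot(inherits(kg, "kg"))
  tr <- kg$triples
  lines <- sprintf("%s\t%s\t%s\t%s", tr$head, tr$relation, tr$tail,
                   tr$provenance)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(nrow(tr))
}

#' Add and remove triples
#'
#' Returns `(kg.triples` \eqn{\cup} `additions) \ removals` as a new graph.
#' New endpoint entities are auto-registered; provenance of additions is
#' preserved; duplicates are silently deduplicated (existing triples win, so
#' original triples are never re-tagged). Removing a triple that is not
#' present logs a warning but is not an error.
#'
#' @param kg a `kg`.
#' @param additions data frame of triples to add (`head`, `relation`, `tail`,
#'   optional `provenance`), or `NULL`.
#' @param removals data frame of triples to remove (`head`, `relation`,
#'   `tail`), or `NULL`.
#' @return A new validated `kg`.
#' @export
merge_triples <- function(kg, additions = NULL, removals = NULL) {
  stopifnot(inherits(kg, "kg"))
  tr <- kg$triples
  if (!is.null(additions) && NROW(additions) > 0) {
    additions <- as.data.frame(additions, stringsAsFactors = FALSE)
    if (is.null(additions$provenance)) additions$provenance <- "original"
    additions <- additions[, c("head", "relation", "tail", "provenance")]
    tr <- rbind(tr, additions)
    tr <- tr[!duplicated(tr[, c("head", "relation", "tail")]), , drop = FALSE]
  }
  if (!is.null(removals) && NROW(removals) > 0) {
    removals <- as.data.frame(removals, stringsAsFactors = FALSE)
    key <- function(d) paste(d$head, d$relation, d$tail, sep = "\r")
    hit <- key(removals) %in% key(tr)
    if (any(!hit)) {
      warning(sum(!hit), " removal(s) not present in graph; ignored")
    }
    tr <- tr[!(key(tr) %in% key(removals)), , drop = FALSE]
  }
  rownames(tr) <- NULL
  # keep entities that lost all their triples registered (no orphan surprise)
  knowledge_graph(tr, kg$schema, extra_entities = kg$entities$id)
}

#' Undirected igraph view of a knowledge graph
#'
#' Edge direction is ignored. With `simple = TRUE` (default) parallel triples
#' between the same unordered node pair collapse to one edge and self-loops
#' are dropped; this is the view used by all topology metrics. With
#' `simple = FALSE` every triple contributes an edge.
#'
#' @param kg a `kg`.
#' @param simple collapse multi-edges and drop loops?
#' @return An `igraph` graph whose vertices are all registered entities.
#' @export
kg_igraph <- function(kg, simple = TRUE) {
  stopifnot(inherits(kg, "kg"))
  g <- igraph::graph_from_data_frame(
    kg$triples[, c("head", "tail")], directed = FALSE,
    vertices = kg$entities$id)
  if (simple) g <- igraph::simplify(g, remove.multiple = TRUE,
                                    remove.loops = TRUE)
  g
}

#' Connected components of the undirected view
#'
#' @param kg a `kg`.
#' @return A list of character vectors of entity ids, one per component,
#'   sorted by decreasing size; ties broken by the lexicographically smallest
#'   member id. Ids within a component are sorted.
#' @export
connected_components <- function(kg) {
  g <- kg_igraph(kg)
  cmp <- igraph::components(g)
  ids <- igraph::V(g)$name
  comps <- split(ids, cmp$membership)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps),
               vapply(comps, `[[`, "", 1))
  unname(comps[ord])
}

#' Export a knowledge graph to GraphML
#'
#' Vertices carry `label` and `type` attributes; edges carry `relation` and
#' `provenance`. Directed edges (head to tail) are written for visualization.
#'
#' @param kg a `kg`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(kg, path) {
  stopifnot(inherits(kg, "kg"))
  g <- igraph::graph_from_data_frame(
    kg$triples[, c("head", "tail", "relation", "provenance")],
    directed = TRUE, vertices = kg$entities)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

triple_key <- function(tr) paste(tr$head, tr$relation, tr$tail, sep = "\r")

#' Triples of a graph as a data frame
#'
#' @param kg a `kg`.
#' @param relation optional relation name filter.
#' @return The triple data frame (columns `head`, `relation`, `tail`,
#'   `provenance`).
#' @export
kg_triples <- function(kg, relation = NULL) {
  tr <- kg$triples
  if (!is.null(relation)) tr <- tr[tr$relation %in% relation, , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Entity ids of a given type
#'
#' @param kg a `kg`.
#' @param type entity type name (e.g. `"Prescription"`).
#' @return Character vector of ids.
#' @export
kg_entities_of_type <- function(kg, type) {
  kg$entities$id[kg$entities$type %in% type]
}
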