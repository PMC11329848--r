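# Ontology schema: entity types, relation specs (domain/range, transitivity,
# symmetry, mutual exclusivity), and an id -> entity-type map.

#' Construct an ontology schema
#'
#' A schema declares the entity types a graph may use, one specification per
#' relation (type constraints plus the three ontology properties: transitive,
#' symmetric, mutually exclusive with another relation), and an optional map
#' from entity ids to entity types. Ids absent from the map default to type
#' `"Other"` when a graph is built.
#'
#' Mutual exclusivity is symmetrized at the schema level: declaring that
#' `Treat` excludes `ContraindicationIs` implies the converse. A relation may
#' not be declared exclusive with itself.
#'
#' @param entity_types character vector of declared entity type names.
#' @param relations data frame with columns `name`, `domain`, `range`
#'   (entity types or `"any"`), logical `transitive`, `symmetric`, and
#'   `exclusive_with` (relation name or `NA`).
#' @param entity_type_map named character vector mapping entity ids to types
#'   (may be empty).
#' @return An object of class `kg_schema`.
#' @examples
#' sch <- kg_schema(
#'   entity_types = c("Syndrome", "Symptom"),
#'   relations = data.frame(name = "Manifest", domain = "Syndrome",
#'                          range = "Symptom", transitive = FALSE,
#'                          symmetric = FALSE, exclusive_with = NA)
#' )
#' @export
kg_schema <- function(entity_types, relations, entity_type_map = character()) {
  stopifnot(is.character(entity_types), length(entity_types) >= 1)
  entity_types <- unique(c(entity_types, "Other"))
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  required <- c("name", "domain", "range", "transitive", "symmetric",
                "exclusive_with")
  missing_cols <- setdiff(required, names(relations))
  for (cl in missing_cols) {
    relations[[cl]] <- switch(cl,
      domain = "any", range = "any",
      transitive = FALSE, symmetric = FALSE,
      exclusive_with = NA_character_,
      stop("relation table lacks required column: ", cl))
  }
  relations <- relations[, required]
  relations$exclusive_with <- as.character(relations$exclusive_with)
  if (anyDuplicated(relations$name)) {
    stop("schema violation: duplicated relation names: ",
         paste(unique(relations$name[duplicated(relations$name)]),
               collapse = ", "))
  }
  bad_type <- setdiff(c(relations$domain, relations$range),
                      c(entity_types, "any"))
  if (length(bad_type)) {
    stop("schema violation: undeclared entity type in domain/range: ",
         paste(bad_type, collapse = ", "))
  }
  if (any(!is.na(relations$exclusive_with) &
          relations$exclusive_with == relations$name)) {
    stop("schema violation: a relation cannot be exclusive with itself")
  }
  unknown_excl <- setdiff(stats::na.omit(relations$exclusive_with),
                          relations$name)
  if (length(unknown_excl)) {
    stop("schema violation: exclusive_with references unknown relation: ",
         paste(unknown_excl, collapse = ", "))
  }
  # symmetrize exclusivity
  for (i in seq_len(nrow(relations))) {
    ew <- relations$exclusive_with[i]
    if (!is.na(ew)) {
      j <- match(ew, relations$name)
      back <- relations$exclusive_with[j]
      if (is.na(back)) {
        relations$exclusive_with[j] <- relations$name[i]
      } else if (back != relations$name[i]) {
        stop("schema violation: exclusivity of ", ew,
             " already points to ", back)
      }
    }
  }
  etm <- as.character(entity_type_map)
  names(etm) <- names(entity_type_map)
  if (length(etm)) {
    bad <- setdiff(unique(etm), entity_types)
    if (length(bad)) {
      stop("schema violation: entity_type_map uses undeclared types: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(entity_types = entity_types, relations = relations,
                 entity_type_map = etm),
            class = "kg_schema")
}

#' Read an ontology schema from JSON
#'
#' Expected layout: `{"entity_types": [...], "relations": [{"name", "domain",
#' "range", "transitive", "symmetric", "exclusive_with"}, ...],
#' "entity_type_map": {"id": "Type", ...}}`. Missing relation fields default
#' to `domain = range = "any"`, both flags `FALSE`, no exclusivity.
#'
#' @param path path to a UTF-8 JSON file.
#' @return A `kg_schema`.
#' @seealso [write_schema()]
#' @export
read_schema <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$entity_types) || is.null(js$relations)) {
    stop("schema file must declare entity_types and relations: ", path)
  }
  rel <- do.call(rbind, lapply(js$relations, function(r) {
    data.frame(
      name = r$name,
      domain = if (is.null(r$domain)) "any" else r$domain,
      range = if (is.null(r$range)) "any" else r$range,
      transitive = isTRUE(r$transitive),
      symmetric = isTRUE(r$symmetric),
      exclusive_with = if (is.null(r$exclusive_with)) NA_character_
                       else r$exclusive_with,
      stringsAsFactors = FALSE)
  }))
  etm <- unlist(js$entity_type_map)
  if (is.null(etm)) etm <- character()
  kg_schema(unlist(js$entity_types), rel, etm)
}

#' Write an ontology schema to JSON
#'
#' @param schema a `kg_schema`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "kg_schema"))
  rels <- lapply(seq_len(nrow(schema$relations)), function(i) {
    r <- as.list(schema$relations[i, ])
    if (is.na(r$exclusive_with)) r$exclusive_with <- NULL
    r
  })
  out <- list(entity_types = schema$entity_types, relations = rels,
              entity_type_map = as.list(schema$entity_type_map))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.kg_schema <- function(x, ...) {
  cat("<kg_schema> ", length(x$entity_types), " entity types, ",
      nrow(x$relations), " relations\n", sep = "")
  props <- character()
  if (any(x$relations$transitive))
    props <- c(props, paste0("transitive: ",
      paste(x$relations$name[x$relations$transitive], collapse = ", ")))
  if (any(x$relations$symmetric))
    props <- c(props, paste0("symmetric: ",
      paste(x$relations$name[x$relations$symmetric], collapse = ", ")))
  ex <- exclusivity_pairs(x)
  if (nrow(ex))
    props <- c(props, paste0("exclusive: ",
      paste(ex$relation_a, "/", ex$relation_b, collapse = ", ")))
  for (p in props) cat(" ", p, "\n")
  invisible(x)
}

#' Mutual-exclusivity pairs declared by a schema
#'
#' @param schema a `kg_schema`.
#' @return data frame with columns `relation_a`, `relation_b`, one row per
#'   unordered exclusive pair (`relation_a < relation_b` lexicographically).
#' @export
exclusivity_pairs <- function(schema) {
  rel <- schema$relations
  keep <- !is.na(rel$exclusive_with) & rel$name < rel$exclusive_with
  data.frame(relation_a = rel$name[keep],
             relation_b = rel$exclusive_with[keep],
             stringsAsFactors = FALSE)
}

entity_type_of <- function(schema, ids) {
  ty <- unname(schema$entity_type_map[ids])
  ty[is.na(ty)] <- "Other"
  ty
}
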