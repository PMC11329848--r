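test_that("schema validation enforces the Table-1 style invariants", {
  expect_error(
    kg_schema("Syndrome",
              data.frame(name = "R", domain = "any", range = "any",
                         transitive = FALSE, symmetric = FALSE,
                         exclusive_with = "R")),
    "exclusive with itself")
  expect_error(
    kg_schema("Syndrome",
              data.frame(name = c("R", "R"), domain = "any", range = "any",
                         transitive = FALSE, symmetric = FALSE,
                         exclusive_with = NA)),
    "duplicated relation")
  expect_error(
    kg_schema("Syndrome",
              data.frame(name = "R", domain = "Ghost", range = "any",
                         transitive = FALSE, symmetric = FALSE,
                         exclusive_with = NA)),
    "undeclared entity type")
  # exclusivity symmetrized at schema level
  sch <- tiny_schema()
  rel <- sch$relations
  expect_identical(rel$exclusive_with[rel$name == "ContraindicationIs"],
                   "Treat")
  expect_identical(exclusivity_pairs(sch)$relation_a, "ContraindicationIs")
})

test_that("schema JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  sch <- tiny_schema()
  write_schema(sch, path)
  sch2 <- read_schema(path)
  expect_identical(sch2$relations, sch$relations)
  expect_setequal(sch2$entity_types, sch$entity_types)
  expect_identical(sort(names(sch2$entity_type_map)),
                   sort(names(sch$entity_type_map)))
})

test_that("load_triples parses, types, deduplicates, and reports errors", {
  sch_path <- withr::local_tempfile(fileext = ".json")
  write_schema(tiny_schema(), sch_path)
  tsv <- withr::local_tempfile(fileext = ".tsv")

  writeLines("S1\tManifest\tX1", tsv)
  kg <- load_triples(tsv, sch_path)
  expect_equal(nrow(kg$entities), 2)
  expect_equal(nrow(kg$triples), 1)
  expect_equal(kg$entities$type[kg$entities$id == "S1"], "Syndrome")

  writeLines(c("S1\tManifest\tX1", "S1\tManifest\tX1"), tsv)
  expect_equal(nrow(load_triples(tsv, sch_path)$triples), 1)

  writeLines("S1\tFly\tX1", tsv)
  expect_error(load_triples(tsv, sch_path), "undeclared relation")

  writeLines(c("S1\tManifest\tX1", "brokenline"), tsv)
  expect_error(load_triples(tsv, sch_path), "line 2")

  # domain/range violation: CorrespondTo requires a Symptom head
  writeLines("S1\tCorrespondTo\tF1", tsv)
  expect_error(load_triples(tsv, sch_path), "domain/range")

  # ids without a type mapping become Other
  writeLines("Mystery\tManifest\tX1", tsv)
  kg <- load_triples(tsv, sch_path)
  expect_equal(kg$entities$type[kg$entities$id == "Mystery"], "Other")
})

test_that("save/load is the identity on the triple set", {
  gen <- generate_kg(small_gen_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- save_triples(gen$kg, path)
  expect_equal(n, nrow(gen$kg$triples))
  kg2 <- load_triples(path, gen$kg$schema)
  expect_setequal(
    paste(kg2$triples$head, kg2$triples$relation, kg2$triples$tail,
          kg2$triples$provenance),
    paste(gen$kg$triples$head, gen$kg$triples$relation,
          gen$kg$triples$tail, gen$kg$triples$provenance))
  # empty graph -> empty file, count 0
  empty <- knowledge_graph(data.frame(), tiny_schema())
  expect_equal(save_triples(empty, path), 0)
  expect_equal(length(readLines(path)), 0)
})

test_that("merge_triples does set arithmetic with provenance preserved", {
  kg <- tiny_kg()
  n0 <- nrow(kg$triples)
  adds <- triples_df(c("S2", "S2", "S3", "S3", "S2"),
                     c("Manifest", "Manifest", "Manifest", "Contain",
                       "Manifest"),
                     c("X2", "X3", "X1", "F1", "X1"),
                     prov = "path_reasoning")
  rems <- kg$triples[1:2, c("head", "relation", "tail")]
  kg2 <- merge_triples(kg, adds, rems)
  expect_equal(nrow(kg2$triples), n0 + 5 - 2)
  expect_true(all(c("S2", "S3", "X2", "X3") %in% kg2$entities$id))
  expect_setequal(unique(kg2$triples$provenance),
                  c("original", "path_reasoning"))

  # duplicates silently deduplicated, existing provenance wins
  kg3 <- merge_triples(kg, kg$triples[1, ])
  expect_equal(nrow(kg3$triples), n0)
  # removal of a non-existent triple warns but proceeds
  expect_warning(
    merge_triples(kg, removals = triples_df("S9", "Manifest", "X9")),
    "not present")
})

test_that("connected_components is a partition and matches union-find", {
  # chain a-b-c plus pair d-e
  sch <- kg_schema("Other",
                   data.frame(name = "R", domain = "any", range = "any",
                              transitive = FALSE, symmetric = FALSE,
                              exclusive_with = NA))
  kg <- knowledge_graph(triples_df(c("a", "b", "d"), "R", c("b", "c", "e")),
                        sch)
  comps <- connected_components(kg)
  expect_equal(comps, list(c("a", "b", "c"), c("d", "e")))

  # single isolated node forms its own singleton component
  kg1 <- knowledge_graph(data.frame(), sch, extra_entities = "lonely")
  expect_equal(connected_components(kg1), list("lonely"))

  # random graphs match the union-find oracle; components partition entities
  for (seed in 1:3) {
    set.seed(seed)
    nodes <- sprintf("n%02d", 1:30)
    m <- 25
    e_from <- sample(nodes, m, replace = TRUE)
    e_to <- sample(nodes, m, replace = TRUE)
    kg_r <- knowledge_graph(triples_df(e_from, "R", e_to), sch,
                            extra_entities = nodes)
    got <- connected_components(kg_r)
    want <- oracle_components(e_from, e_to, nodes)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    expect_setequal(unlist(got), nodes)      # covers all entities
    expect_equal(anyDuplicated(unlist(got)), 0)  # disjoint
    expect_true(all(diff(lengths(got)) <= 0))    # sorted by size
  }
})

test_that("graphml export writes a parseable file", {
  kg <- tiny_kg()
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(kg, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(kg$entities))
  expect_equal(igraph::ecount(g), nrow(kg$triples))
})
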