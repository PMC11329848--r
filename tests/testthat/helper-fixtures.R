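# Shared fixtures: a minimal hand-built schema/graph and a relation-pattern
# fixture for embedding tests. All fixtures are built in code.

tiny_schema <- function() {
  kg_schema(
    entity_types = c("Syndrome", "SubSyndrome", "Symptom",
                     "PathogenesisFactor", "Prescription"),
    relations = data.frame(
      name = c("Manifest", "Contain", "CorrespondTo", "Treat",
               "DifferentialDiagnosisIs", "ContraindicationIs"),
      domain = c("any", "any", "Symptom", "Prescription", "any",
                 "Prescription"),
      range = c("Symptom", "any", "PathogenesisFactor", "any", "any", "any"),
      transitive = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      symmetric = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
      exclusive_with = c(NA, NA, NA, "ContraindicationIs", NA, "Treat"),
      stringsAsFactors = FALSE),
    entity_type_map = c(S1 = "Syndrome", S2 = "Syndrome", S3 = "Syndrome",
                        X1 = "Symptom", X2 = "Symptom", X3 = "Symptom",
                        F1 = "PathogenesisFactor", F2 = "PathogenesisFactor",
                        P1 = "Prescription", P2 = "Prescription"))
}

tiny_kg <- function(triples = NULL) {
  if (is.null(triples)) {
    triples <- data.frame(
      head = c("S1", "S1", "X1", "S1", "P1"),
      relation = c("Manifest", "Contain", "CorrespondTo", "Contain",
                   "Treat"),
      tail = c("X1", "F1", "F1", "F2", "S1"),
      stringsAsFactors = FALSE)
  }
  knowledge_graph(triples, tiny_schema())
}

triples_df <- function(h, r, t, prov = "original") {
  data.frame(head = h, relation = r, tail = t, provenance = prov,
             stringsAsFactors = FALSE)
}

# relation-pattern fixture: symmetric pairs (one direction trained, reverse
# held out), an antisymmetric chain, and one-to-many hubs
pattern_fixture <- function(n_ent = 40, n_sym = 30, seed = 1) {
  set.seed(seed)
  ents <- sprintf("e%02d", seq_len(n_ent))
  pairs <- t(replicate(n_sym, sample(ents, 2)))
  sym_f <- data.frame(head = pairs[, 1], relation = "sym",
                      tail = pairs[, 2], stringsAsFactors = FALSE)
  sym_r <- data.frame(head = pairs[, 2], relation = "sym",
                      tail = pairs[, 1], stringsAsFactors = FALSE)
  perm <- sample(ents)
  anti <- data.frame(head = perm[-n_ent], relation = "next",
                     tail = perm[-1], stringsAsFactors = FALSE)
  hub <- sample(ents, 4)
  o2m <- do.call(rbind, lapply(hub, function(h)
    data.frame(head = h, relation = "has",
               tail = sample(setdiff(ents, h), 8),
               stringsAsFactors = FALSE)))
  vi <- sample(n_sym, n_sym %/% 2)
  list(train = rbind(sym_f, sym_r[-vi, ], anti, o2m),
       valid_sym = sym_r[vi, ], entities = ents)
}

# small synthetic configs used across tests (kept small for speed)
small_gen_config <- function(seed = 11, ...) {
  generator_config(n_syndromes = 15, n_subsyndromes = 4, n_symptoms = 90,
                   n_factors = 25, n_prescriptions = 40, n_dd_pairs = 6,
                   n_planted_missing = 30, n_planted_contradictions = 3,
                   n_isolated_components = 3, seed = seed, ...)
}
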