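# Synthetic syndrome-symptom-pathogenesis-prescription graphs with a
# planted-truth ledger: withheld true triples (recoverable by path or
# ontology reasoning), planted contradictions, planted isolated components,
# and planted syndrome -> symptom association rules for record mining.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default ontology schema for synthetic graphs
#'
#' Declares the seven entity types and the six relations used by the
#' generator: `Manifest` (syndrome shows symptom), `Contain` (transitive;
#' syndrome hierarchy and syndrome-to-pathogenesis-factor composition),
#' `CorrespondTo` (symptom maps to pathogenesis factor), `Treat`
#' (prescription treats syndrome/symptom/subsyndrome), symmetric
#' `DifferentialDiagnosisIs`, and `ContraindicationIs`, mutually exclusive
#' with `Treat`.
#'
#' @param entity_type_map optional id-to-type map to attach.
#' @return A [kg_schema()].
#' @export
default_schema <- function(entity_type_map = character()) {
  kg_schema(
    entity_types = c("Syndrome", "SubSyndrome", "Symptom",
                     "PathogenesisFactor", "Prescription",
                     "TreatmentMethod", "Other"),
    relations = data.frame(
      name = c("Manifest", "Contain", "CorrespondTo", "Treat",
               "DifferentialDiagnosisIs", "ContraindicationIs",
               "TreatmentMethodIs"),
      domain = c("any", "any", "Symptom", "Prescription", "any",
                 "Prescription", "any"),
      range = c("Symptom", "any", "PathogenesisFactor", "any", "any",
                "any", "TreatmentMethod"),
      transitive = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      symmetric = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
      exclusive_with = c(NA, NA, NA, "ContraindicationIs", NA, "Treat", NA),
      stringsAsFactors = FALSE),
    entity_type_map = entity_type_map)
}

#' Generator configuration
#'
#' Defaults emulate the scale and structure of a small classical-text
#' knowledge graph (around 1100 nodes and 4000-4500 triples): a few dozen
#' syndromes over a pool of several hundred symptoms, pathogenesis factors
#' with heavy-tailed popularity (preferential attachment), prescriptions
#' treating one syndrome each, and a handful of planted defects of every
#' kind the completion stages are meant to repair.
#'
#' @param n_syndromes,n_subsyndromes,n_symptoms,n_factors,n_prescriptions
#'   entity pool sizes.
#' @param p_manifest probability that a syndrome manifests each symptom whose
#'   pathogenesis factor it contains.
#' @param p_treat_symptom probability that a prescription also treats one of
#'   its syndrome's symptoms.
#' @param factors_per_syndrome integer range (length 2) of factors contained
#'   per syndrome.
#' @param n_dd_pairs number of differential-diagnosis syndrome pairs (one
#'   direction emitted; the reverse is ontology-recoverable).
#' @param n_planted_missing number of true Manifest triples withheld (each is
#'   guaranteed a surviving 2-step evidence path for path reasoning).
#' @param n_planted_contradictions number of Treat/ContraindicationIs pairs
#'   planted on the same (prescription, syndrome) pair.
#' @param n_isolated_components number of small components disconnected from
#'   the giant component; roughly two-thirds are Fangzheng (subsyndrome)
#'   components, the rest treatment-method components left uncompleted.
#' @param rule_table data frame with columns `syndrome` (id), `symptoms`
#'   (list column of symptom ids) and `penetrance`; `NULL` plants rules on
#'   three syndromes with prevalences 0.45/0.35/0.20 and penetrance 0.8,
#'   emulating a strongly imbalanced case mix.
#' @param prevalence syndrome mixing weights for record generation, parallel
#'   to `rule_table` rows.
#' @param seed integer seed; identical configs give identical output.
#' @return A list of class `kg_generator_config`.
#' @export
generator_config <- function(n_syndromes = 60, n_subsyndromes = 10,
                             n_symptoms = 600, n_factors = 150,
                             n_prescriptions = 280,
                             p_manifest = 0.85, p_treat_symptom = 0.3,
                             factors_per_syndrome = c(4L, 12L),
                             n_dd_pairs = 20,
                             n_planted_missing = 60,
                             n_planted_contradictions = 8,
                             n_isolated_components = 6,
                             rule_table = NULL,
                             prevalence = c(0.45, 0.35, 0.20),
                             seed = 1L) {
  cfg <- list(n_syndromes = n_syndromes, n_subsyndromes = n_subsyndromes,
              n_symptoms = n_symptoms, n_factors = n_factors,
              n_prescriptions = n_prescriptions, p_manifest = p_manifest,
              p_treat_symptom = p_treat_symptom,
              factors_per_syndrome = as.integer(factors_per_syndrome),
              n_dd_pairs = n_dd_pairs,
              n_planted_missing = n_planted_missing,
              n_planted_contradictions = n_planted_contradictions,
              n_isolated_components = n_isolated_components,
              rule_table = rule_table, prevalence = prevalence,
              seed = as.integer(seed))
  counts <- cfg[c("n_syndromes", "n_subsyndromes", "n_symptoms", "n_factors",
                  "n_prescriptions", "n_dd_pairs", "n_planted_missing",
                  "n_planted_contradictions", "n_isolated_components")]
  stopifnot(all(unlist(counts) >= 0),
            p_manifest >= 0, p_manifest <= 1,
            p_treat_symptom >= 0, p_treat_symptom <= 1,
            length(cfg$factors_per_syndrome) == 2)
  class(cfg) <- "kg_generator_config"
  cfg
}

pref_sample <- function(pool, size, weights) {
  # weighted sampling without replacement; weights follow popularity so the
  # resulting degree distribution is heavy-tailed
  if (size >= length(pool)) return(pool)
  sample(pool, size, prob = weights[pool] + 1)
}

#' Generate a synthetic knowledge graph with a planted-truth ledger
#'
#' See [generator_config()] for what is planted. The returned ledger records
#' every planted item: withheld Manifest triples (all with a surviving
#' Contain/CorrespondTo evidence path), withheld Contain closure triples and
#' reverse differential-diagnosis triples (ontology-recoverable),
#' contradiction pairs, isolated component memberships with their category,
#' and the realized rule table. Generation fails if any withheld triple is
#' not recoverable by at least one mechanism.
#'
#' @param config a [generator_config()].
#' @return list with elements `kg` (a [knowledge_graph()]) and `ledger`
#'   (class `kg_ledger`).
#' @export
generate_kg <- function(config = generator_config()) {
  stopifnot(inherits(config, "kg_generator_config"))
  with_seed(config$seed, generate_kg_impl(config))
}

generate_kg_impl <- function(cfg) {
  syn <- sprintf("S%03d", seq_len(cfg$n_syndromes))
  sym <- sprintf("X%04d", seq_len(cfg$n_symptoms))
  fac <- sprintf("PF%03d", seq_len(cfg$n_factors))
  rx  <- sprintf("P%03d", seq_len(cfg$n_prescriptions))

  tr <- list()
  add <- function(h, r, t) {
    if (length(h)) tr[[length(tr) + 1]] <<- data.frame(
      head = h, relation = r, tail = t, provenance = "original",
      stringsAsFactors = FALSE)
  }

  # symptom -> factor (CorrespondTo), preferential so factor popularity is
  # heavy-tailed
  fac_w <- stats::setNames(numeric(length(fac)), fac)
  sym_factor <- character(length(sym))
  for (i in seq_along(sym)) {
    f <- sample(fac, 1, prob = fac_w + 1)
    sym_factor[i] <- f
    fac_w[f] <- fac_w[f] + 1
  }
  names(sym_factor) <- sym
  add(sym, "CorrespondTo", sym_factor)

  # syndrome hierarchy: chains of three, closure withheld
  withheld_ont <- list()
  chain_of <- rep(NA_character_, length(syn))
  names(chain_of) <- syn
  n_chain <- cfg$n_syndromes %/% 3
  if (n_chain > 0) {
    for (c_i in seq_len(n_chain)) {
      trio <- syn[(3 * c_i - 2):(3 * c_i)]
      add(trio[1], "Contain", trio[2])
      add(trio[2], "Contain", trio[3])
    }
  }

  # syndrome -> factor composition
  syn_fac <- vector("list", length(syn))
  names(syn_fac) <- syn
  for (s in syn) {
    k <- sample(seq(cfg$factors_per_syndrome[1],
                    cfg$factors_per_syndrome[2]), 1)
    syn_fac[[s]] <- pref_sample(fac, k, fac_w)
    add(s, "Contain", syn_fac[[s]])
  }

  # manifestation: a syndrome shows the symptoms of its factors
  man_h <- character(); man_t <- character()
  for (s in syn) {
    pool <- sym[sym_factor %in% syn_fac[[s]]]
    keep <- pool[stats::runif(length(pool)) < cfg$p_manifest]
    man_h <- c(man_h, rep(s, length(keep)))
    man_t <- c(man_t, keep)
  }
  manifest <- data.frame(head = man_h, relation = "Manifest", tail = man_t,
                         provenance = "original", stringsAsFactors = FALSE)

  # withhold Manifest triples that keep a 2-step evidence path
  # (S -Contain-> PF <-CorrespondTo- X, both of which survive)
  n_miss <- min(cfg$n_planted_missing, nrow(manifest))
  withheld_idx <- if (n_miss > 0) sample(nrow(manifest), n_miss) else integer()
  withheld_manifest <- manifest[withheld_idx, , drop = FALSE]
  withheld_manifest$provenance <- "path_reasoning"
  rownames(withheld_manifest) <- NULL
  manifest <- manifest[setdiff(seq_len(nrow(manifest)), withheld_idx), ,
                       drop = FALSE]
  rownames(manifest) <- NULL
  tr[[length(tr) + 1]] <- manifest

  # prescriptions: one treated syndrome each, sometimes a treated symptom
  rx_syn <- sample(syn, length(rx), replace = TRUE)
  add(rx, "Treat", rx_syn)
  man_by_syn <- split(manifest$tail, manifest$head)
  for (i in seq_along(rx)) {
    if (stats::runif(1) < cfg$p_treat_symptom) {
      pool <- man_by_syn[[rx_syn[i]]]
      if (length(pool)) add(rx[i], "Treat", sample(pool, 1))
    }
  }

  # differential diagnosis: one direction only; reverse is withheld
  # (symmetry-recoverable)
  withheld_sym <- NULL
  if (cfg$n_dd_pairs > 0 && length(syn) >= 2) {
    pairs <- t(replicate(cfg$n_dd_pairs, sample(syn, 2)))
    a <- pmin(pairs[, 1], pairs[, 2])
    b <- pmax(pairs[, 1], pairs[, 2])
    keep <- !duplicated(paste(a, b))
    a <- a[keep]; b <- b[keep]
    add(a, "DifferentialDiagnosisIs", b)
    withheld_sym <- data.frame(head = b,
                               relation = "DifferentialDiagnosisIs",
                               tail = a,
                               provenance = "ontology_reasoning",
                               stringsAsFactors = FALSE)
  }

  # planted contradictions: prescription both treats and is contraindicated
  # for the same syndrome
  n_con <- min(cfg$n_planted_contradictions, length(rx))
  con_idx <- if (n_con > 0) sample(length(rx), n_con) else integer()
  contradiction_pairs <- data.frame(
    head = rx[con_idx], tail = rx_syn[con_idx],
    relation_a = rep("ContraindicationIs", n_con),
    relation_b = rep("Treat", n_con), stringsAsFactors = FALSE)
  add(rx[con_idx], "ContraindicationIs", rx_syn[con_idx])

  # bridge accidental stray components into the giant component so the
  # planted isolated components below are the only isolation in the graph:
  # stray factors get contained by an anchor syndrome, stray syndromes get a
  # differential-diagnosis link (reverse withheld like the others)
  main <- do.call(rbind, tr)
  g0 <- igraph::graph_from_data_frame(main[c("head", "tail")],
                                      directed = FALSE)
  cmp <- igraph::components(g0)
  anchor <- syn[1]
  giant <- cmp$membership[[anchor]]
  node_type <- function(id) {
    if (id %in% fac) "factor" else if (id %in% syn) "syndrome" else "other"
  }
  for (ci in setdiff(unique(cmp$membership), giant)) {
    ids <- names(cmp$membership)[cmp$membership == ci]
    f_in <- intersect(ids, fac)
    s_in <- intersect(ids, syn)
    if (length(f_in)) {
      add(anchor, "Contain", f_in[1])
    } else if (length(s_in)) {
      add(anchor, "DifferentialDiagnosisIs", s_in[1])
      withheld_sym <- rbind(withheld_sym, data.frame(
        head = s_in[1], relation = "DifferentialDiagnosisIs", tail = anchor,
        provenance = "ontology_reasoning", stringsAsFactors = FALSE))
    } else {
      add(anchor, "Contain", ids[1])
    }
  }
  # entities never mentioned in a triple (unused factors) join via Contain
  mentioned <- unique(c(main$head, main$tail))
  for (f0 in setdiff(fac, mentioned)) add(anchor, "Contain", f0)

  # isolated components: Fangzheng ("<prescription id> Syndrome") components
  # re-linkable by the name-pattern resolver, plus treatment-method
  # components that stay uncompleted
  iso_components <- list()
  iso_hints <- character()
  n_iso <- cfg$n_isolated_components
  n_fz <- min(ceiling(2 * n_iso / 3), cfg$n_subsyndromes)
  fz_rx <- rx[seq_len(n_fz)]
  sub_ids <- character()
  tm_ids <- character()
  iso_sym <- character()
  k_sym <- 0
  for (i in seq_len(n_iso)) {
    if (i <= n_fz) {
      sid <- paste(fz_rx[i], "Syndrome")
      sub_ids <- c(sub_ids, sid)
      nsym <- sample(1:3, 1)
      xs <- sprintf("XI%03d", k_sym + seq_len(nsym))
      k_sym <- k_sym + nsym
      iso_sym <- c(iso_sym, xs)
      add(sid, "Manifest", xs)
      iso_components[[i]] <- c(sid, xs)
      iso_hints[i] <- "SubSyndrome"
    } else {
      tm <- sprintf("TM%03d", i)
      ot <- sprintf("OT%03d", i)
      tm_ids <- c(tm_ids, tm)
      add(ot, "TreatmentMethodIs", tm)
      iso_components[[i]] <- c(tm, ot)
      iso_hints[i] <- "Other"
    }
  }
  other_ids <- if (n_iso > n_fz) sprintf("OT%03d", (n_fz + 1):n_iso)
               else character()

  triples <- do.call(rbind, tr)
  triples <- triples[!duplicated(triples[, c("head", "relation", "tail")]), ]
  rownames(triples) <- NULL

  etm <- c(stats::setNames(rep("Syndrome", length(syn)), syn),
           stats::setNames(rep("Symptom", length(sym)), sym),
           stats::setNames(rep("Symptom", length(iso_sym)), iso_sym),
           stats::setNames(rep("PathogenesisFactor", length(fac)), fac),
           stats::setNames(rep("Prescription", length(rx)), rx),
           stats::setNames(rep("SubSyndrome", length(sub_ids)), sub_ids),
           stats::setNames(rep("TreatmentMethod", length(tm_ids)), tm_ids),
           stats::setNames(rep("Other", length(other_ids)), other_ids))
  schema <- default_schema(etm)
  kg <- knowledge_graph(triples, schema)

  # withheld ontology triples: full transitive closure complement of Contain
  # plus the reverse differential-diagnosis directions
  closure_missing <- transitive_closure(kg, "Contain")
  withheld_ontology <- rbind(closure_missing, withheld_sym)

  # rule table for record mining
  rule_table <- cfg$rule_table
  if (is.null(rule_table)) {
    cand <- names(man_by_syn)[lengths(man_by_syn) >= 5]
    rs <- cand[seq_len(min(3, length(cand)))]
    rule_table <- data.frame(syndrome = rs, stringsAsFactors = FALSE)
    # each rule mixes symptoms already in the graph, withheld ones
    # (path-recoverable), and one ontology-underivable symptom whose factor
    # the syndrome does not contain: knowledge only record mining can add
    rule_table$symptoms <- lapply(rs, function(s) {
      wsym <- withheld_manifest$tail[withheld_manifest$head == s]
      tacit_pool <- sym[!(sym_factor %in% syn_fac[[s]])]
      unique(c(sample(man_by_syn[[s]], sample(3:5, 1)),
               utils::head(wsym, 2),
               if (length(tacit_pool)) sample(tacit_pool, 1)))
    })
    rule_table$penetrance <- rep(0.8, length(rs))
  }

  ledger <- structure(list(
    withheld_manifest = withheld_manifest,
    withheld_ontology = withheld_ontology,
    contradiction_pairs = contradiction_pairs,
    isolated_components = iso_components,
    isolated_hints = iso_hints,
    rules = rule_table,
    prevalence = cfg$prevalence,
    seed = cfg$seed), class = "kg_ledger")
  verify_ledger(kg, ledger)
  list(kg = kg, ledger = ledger)
}

# every withheld triple must be recoverable: Manifest by a surviving 2-step
# path, ontology triples by a closure rule
verify_ledger <- function(kg, ledger) {
  wm <- ledger$withheld_manifest
  if (NROW(wm)) {
    contain <- kg_triples(kg, "Contain")
    corr <- kg_triples(kg, "CorrespondTo")
    ckey <- paste(contain$head, contain$tail)
    for (i in seq_len(nrow(wm))) {
      pf <- corr$tail[corr$head == wm$tail[i]]
      if (!any(paste(wm$head[i], pf) %in% ckey)) {
        stop("generation error: withheld Manifest triple (", wm$head[i],
             ", ", wm$tail[i], ") has no surviving evidence path")
      }
    }
    present <- triple_key(wm) %in% triple_key(kg$triples)
    if (any(present)) stop("generation error: withheld triple present in KG")
  }
  invisible(TRUE)
}

#' @export
print.kg_ledger <- function(x, ...) {
  cat("<kg_ledger> withheld Manifest: ", NROW(x$withheld_manifest),
      "; withheld ontology: ", NROW(x$withheld_ontology),
      "; contradictions: ", NROW(x$contradiction_pairs),
      "; isolated components: ", length(x$isolated_components),
      "; planted rules: ", NROW(x$rules), "\n", sep = "")
  invisible(x)
}

#' Serialize / read a planted-truth ledger as JSON
#'
#' @param ledger a `kg_ledger`.
#' @param path file path.
#' @return `path` (write) or a `kg_ledger` (read).
#' @export
write_ledger <- function(ledger, path) {
  out <- unclass(ledger)
  out$rules <- lapply(seq_len(NROW(ledger$rules)), function(i) list(
    syndrome = ledger$rules$syndrome[i],
    symptoms = ledger$rules$symptoms[[i]],
    penetrance = ledger$rules$penetrance[i]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  rules <- js$rules
  if (is.data.frame(rules)) {
    rules$symptoms <- lapply(rules$symptoms, unlist)
  } else if (is.list(rules) && length(rules)) {
    rules <- data.frame(
      syndrome = vapply(rules, `[[`, "", "syndrome"),
      penetrance = vapply(rules, `[[`, 0, "penetrance"),
      stringsAsFactors = FALSE)
    rules$symptoms <- lapply(js$rules, function(r) unlist(r$symptoms))
  }
  js$rules <- rules
  js$isolated_components <- lapply(js$isolated_components, unlist)
  structure(js, class = "kg_ledger")
}

#' Generate synthetic medical-record transactions
#'
#' Each record carries exactly one syndrome label plus symptoms: each rule
#' symptom of the drawn syndrome is included independently with the rule's
#' penetrance, and each symptom of the graph's symptom pool is added as noise
#' independently with probability `noise`. Syndromes are drawn with the given
#' prevalence weights, so the case mix can be made strongly imbalanced.
#'
#' @param kg a `kg` (supplies the symptom pool for noise).
#' @param rules rule table (`syndrome`, list column `symptoms`, `penetrance`),
#'   e.g. the `rules` element of a generator ledger.
#' @param n_records number of transactions.
#' @param noise per-symptom inclusion probability for noise symptoms.
#' @param prevalence mixing weights over `rules$syndrome` (normalized);
#'   default uniform.
#' @param seed integer seed.
#' @return A list of character vectors (class `kg_transactions`); the first
#'   element of each vector is the syndrome label.
#' @export
generate_records <- function(kg, rules, n_records = 470, noise = 0.01,
                             prevalence = NULL, seed = 1L) {
  stopifnot(inherits(kg, "kg"), NROW(rules) >= 1, n_records >= 0,
            noise >= 0, noise <= 1)
  if (n_records == 0) return(structure(list(), class = "kg_transactions"))
  if (is.null(prevalence)) prevalence <- rep(1, nrow(rules))
  stopifnot(length(prevalence) == nrow(rules))
  pool <- kg_entities_of_type(kg, "Symptom")
  with_seed(seed, {
    draws <- sample(nrow(rules), n_records, replace = TRUE,
                    prob = prevalence)
    recs <- lapply(draws, function(i) {
      syms <- rules$symptoms[[i]]
      keep <- syms[stats::runif(length(syms)) < rules$penetrance[i]]
      noise_syms <- pool[stats::runif(length(pool)) < noise]
      unique(c(rules$syndrome[i], keep, noise_syms))
    })
    structure(recs, class = "kg_transactions")
  })
}

#' Write / read transactions as one tab-separated record per line
#'
#' @param records a list of character vectors.
#' @param path file path.
#' @return `path` (write) or a `kg_transactions` list (read).
#' @export
write_records <- function(records, path) {
  writeLines(vapply(records, paste, "", collapse = "\t"), path,
             useBytes = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  structure(strsplit(lines[nzchar(lines)], "\t", fixed = TRUE),
            class = "kg_transactions")
}
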