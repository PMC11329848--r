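# Quality evaluation, dimensions 1-2: completeness (network topology:
# counts, degrees, density, log-log degree slope) and accuracy
# (contradiction count, closeness-centrality and k-core agreement with
# prior knowledge). All topology uses the undirected view; by default the
# edge count M equals the triple count (the convention under which the
# reference Table-4 style figures <k> = 2M/N and rho = 2M/(N(N-1)) come
# out), with a deduplicated-pair mode behind `edge_mode = "simple"`.

round_half_up <- function(x, digits = 4) {
  # report-style rounding: halves away from zero, unlike round()'s banker's
  # rounding
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Average degree 2M/N
#'
#' @param n node count (>= 1).
#' @param m edge count.
#' @param digits report rounding (default 4).
#' @return `2 m / n`, rounded half-up.
#' @examples
#' average_degree(1255, 4519)  # 7.2016
#' @export
average_degree <- function(n, m, digits = 4) {
  if (n < 1) stop("usage error: need at least one node")
  round_half_up(2 * m / n, digits)
}

#' Network density 2M/(N(N-1))
#'
#' Ratio of the number of edges to the maximum possible number of edges of
#' an undirected simple graph; a value near zero marks a sparse network.
#'
#' @param n node count (>= 2).
#' @param m edge count.
#' @param digits report rounding (default 4).
#' @return Density in `[0, 1]`, rounded half-up.
#' @examples
#' network_density(1255, 4519)  # 0.0057
#' @export
network_density <- function(n, m, digits = 4) {
  if (n < 2) stop("usage error: density needs at least two nodes")
  round_half_up(2 * m / (n * (n - 1)), digits)
}

#' Least-squares slope of the log-log degree distribution
#'
#' Fits `log10(count) ~ log10(degree)` over the nonzero histogram bins with
#' degree >= 1. A clearly negative slope is the signature of a heavy-tailed
#' (power-law-like) degree distribution.
#'
#' @param degrees integer vector of node degrees.
#' @return Slope (NA when fewer than 2 distinct positive degrees).
#' @export
degree_slope <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tb <- table(degrees)
  if (length(tb) < 2) return(NA_real_)
  x <- log10(as.numeric(names(tb)))
  y <- log10(as.numeric(tb))
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Completeness report: topology of a knowledge graph
#'
#' @param kg a `kg`.
#' @param edge_mode `"triples"` (default; M = number of triples) or
#'   `"simple"` (M = number of distinct unordered endpoint pairs).
#' @return List of class `kg_completeness` with `n_nodes`, `n_edges`,
#'   `k_max`, `k_avg`, `density`, `degree_slope`.
#' @export
completeness_report <- function(kg, edge_mode = c("triples", "simple")) {
  edge_mode <- match.arg(edge_mode)
  g <- kg_igraph(kg)  # simple undirected view for degrees
  n <- igraph::vcount(g)
  m <- if (edge_mode == "triples") nrow(kg$triples) else igraph::ecount(g)
  deg <- igraph::degree(g)
  dens <- if (n >= 2) network_density(n, m) else {
    warning("single-node graph: density undefined, reported as 0")
    0
  }
  structure(list(n_nodes = n, n_edges = m,
                 k_max = if (n) max(deg) else 0L,
                 k_avg = average_degree(max(n, 1), m),
                 density = dens,
                 degree_slope = degree_slope(deg),
                 edge_mode = edge_mode),
            class = "kg_completeness")
}

#' @export
print.kg_completeness <- function(x, ...) {
  cat("<completeness> N=", x$n_nodes, " M=", x$n_edges, " (", x$edge_mode,
      ") k_max=", x$k_max, " <k>=", x$k_avg, " density=", x$density,
      " slope=", round(x$degree_slope, 4), "\n", sep = "")
  invisible(x)
}

#' Closeness centrality with component-size scaling
#'
#' `CC(i) = (N_c - 1) / sum_j d_ij` within node i's connected component of
#' size `N_c`, scaled by `(N_c - 1)/(N - 1)` so values are comparable across
#' components (the scaling is a no-op on a connected graph). Isolated nodes
#' score 0. Distances are shortest paths on the undirected simple view.
#'
#' @param kg a `kg`.
#' @param nodes entity ids (default all).
#' @return Named numeric vector of centralities.
#' @export
closeness_centrality <- function(kg, nodes = kg$entities$id) {
  unknown <- setdiff(nodes, kg$entities$id)
  if (length(unknown)) {
    stop("lookup error: unknown node(s): ", paste(unknown, collapse = ", "))
  }
  g <- kg_igraph(kg)
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  memb <- comp$membership
  d <- igraph::distances(g, v = nodes)
  out <- vapply(seq_along(nodes), function(i) {
    nc <- comp$csize[memb[[nodes[i]]]]
    if (nc <= 1 || n <= 1) return(0)
    dd <- d[i, ]
    dd <- dd[is.finite(dd)]
    s <- sum(dd)
    if (s == 0) return(0)
    ((nc - 1) / s) * ((nc - 1) / (n - 1))
  }, 0)
  stats::setNames(out, nodes)
}

#' Top-k closeness ranking and prior-knowledge agreement
#'
#' Ranks entities of one type by closeness centrality (descending, ties by
#' label ascending) and reports which fraction of the top `k` belong to the
#' prior set (e.g. core prescriptions from a reference textbook).
#'
#' @param kg a `kg`.
#' @param entity_type e.g. `"Prescription"`.
#' @param k size of the head of the ranking (default 20).
#' @param prior character vector of prior-knowledge labels (nonempty).
#' @return List with `ranking` (data frame `id`, `closeness`) and
#'   `proportion`.
#' @export
top_closeness_proportion <- function(kg, entity_type, k = 20, prior) {
  if (!length(prior)) stop("usage error: empty prior set")
  ids <- kg_entities_of_type(kg, entity_type)
  if (length(ids) < k) {
    warning("fewer than k entities of type ", entity_type, "; using all ",
            length(ids))
    k <- length(ids)
  }
  cc <- closeness_centrality(kg, ids)
  ord <- order(-cc, ids)
  ranking <- data.frame(id = ids[ord], closeness = unname(cc[ord]),
                        stringsAsFactors = FALSE)
  top <- ranking$id[seq_len(k)]
  list(ranking = ranking,
       proportion = round_half_up(sum(top %in% prior) / k))
}

#' Maximum k-core of one entity type and prior agreement
#'
#' Core numbers are computed on the undirected simple view (iterative
#' minimum-degree peeling). Returns the maximum core number, the entities of
#' `entity_type` sitting in that innermost core, and the fraction of them
#' that belong to the prior set (e.g. symptoms of a reference syndrome),
#' rounded to 4 decimals.
#'
#' @param kg a `kg` with at least one edge.
#' @param entity_type e.g. `"Symptom"`.
#' @param prior character vector of prior labels (may be empty only if the
#'   proportion is not of interest).
#' @return List with `max_kcore`, `nodes` (sorted ids), `proportion`.
#' @export
kcore_analysis <- function(kg, entity_type, prior = character()) {
  g <- kg_igraph(kg)
  if (igraph::ecount(g) == 0) stop("usage error: edgeless graph")
  core <- igraph::coreness(g)
  kmax <- max(core)
  in_core <- names(core)[core == kmax]
  ty <- kg$entities$type[match(in_core, kg$entities$id)]
  nodes <- sort(in_core[ty == entity_type])
  prop <- if (length(nodes)) {
    round_half_up(sum(nodes %in% prior) / length(nodes))
  } else NA_real_
  list(max_kcore = kmax, nodes = nodes, proportion = prop)
}

#' Accuracy report
#'
#' Bundles the contradiction count (via [detect_contradictions()]), the
#' top-k closeness prior agreement for prescriptions and the maximum-k-core
#' prior agreement for symptoms.
#'
#' @param kg a `kg`.
#' @param prior list with elements `core_prescriptions` and
#'   `exterior_symptoms` (character vectors; either may be empty, skipping
#'   the corresponding proportion).
#' @param k top-k for the closeness ranking (default 20).
#' @return List of class `kg_accuracy`.
#' @export
accuracy_report <- function(kg, prior = list(), k = 20) {
  con <- detect_contradictions(kg)
  cc_part <- if (length(prior$core_prescriptions)) {
    top_closeness_proportion(kg, "Prescription", k, prior$core_prescriptions)
  } else NULL
  kc_part <- if (nrow(kg$triples)) {
    kcore_analysis(kg, "Symptom", prior$exterior_symptoms %||% character())
  } else NULL
  structure(list(
    contradiction_count = nrow(con),
    contradictions = con,
    top_closeness = cc_part,
    kcore = kc_part), class = "kg_accuracy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kg_accuracy <- function(x, ...) {
  cat("<accuracy> contradictions=", x$contradiction_count, sep = "")
  if (!is.null(x$top_closeness)) {
    cat(" | top-CC prior proportion=", x$top_closeness$proportion, sep = "")
  }
  if (!is.null(x$kcore)) {
    cat(" | max k-core=", x$kcore$max_kcore, " (", length(x$kcore$nodes),
        " symptoms, prior proportion=", x$kcore$proportion, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
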