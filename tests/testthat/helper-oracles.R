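# Independent oracles, deliberately implemented with different algorithms
# than the package (union-find, BFS, repeated peeling, Warshall, exhaustive
# enumeration, brute-force path products).

oracle_components <- function(edges_from, edges_to, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    a <- find(edges_from[i]); b <- find(edges_to[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

oracle_bfs_dist <- function(adj, start) {
  # adj: named list node -> neighbors
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier])),
                   names(dist)[is.finite(dist)])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

oracle_closeness <- function(adj, node, n_total) {
  dist <- oracle_bfs_dist(adj, node)
  reach <- dist[is.finite(dist)]
  nc <- length(reach)  # includes the node itself
  if (nc <= 1) return(0)
  ((nc - 1) / sum(reach)) * ((nc - 1) / (n_total - 1))
}

oracle_core_numbers <- function(adj) {
  # repeated minimum-degree peeling
  deg <- lengths(adj)
  core <- stats::setNames(rep(0L, length(adj)), names(adj))
  alive <- names(adj)
  k <- 0L
  while (length(alive)) {
    repeat {
      dmin <- vapply(alive, function(v)
        sum(adj[[v]] %in% alive), 0L)
      peel <- alive[dmin <= k]
      if (!length(peel)) break
      core[peel] <- k
      alive <- setdiff(alive, peel)
      if (!length(alive)) break
    }
    k <- k + 1L
  }
  core
}

oracle_warshall <- function(edges, nodes) {
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  reach[cbind(edges$head, edges$tail)] <- TRUE
  for (k in nodes) for (i in nodes) {
    if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
  }
  reach
}

oracle_frequent_itemsets <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  stopifnot(length(items) <= 14)
  n <- length(transactions)
  out <- list()
  for (size in seq_along(items)) {
    for (comb in utils::combn(items, size, simplify = FALSE)) {
      sup <- mean(vapply(transactions, function(tx) all(comb %in% tx), TRUE))
      if (sup >= min_support) {
        out[[paste(comb, collapse = "\037")]] <- sup
      }
    }
  }
  out
}

# brute-force path-product enumeration of P(s -> t; feature)
oracle_path_prob <- function(triples, source, feature, target) {
  probe <- function(node, step) {
    if (step > length(feature$relations)) {
      return(as.numeric(node == target))
    }
    rel <- feature$relations[step]
    if (feature$directions[step] == "forward") {
      nb <- triples$tail[triples$head == node & triples$relation == rel]
    } else {
      nb <- triples$head[triples$tail == node & triples$relation == rel]
    }
    if (!length(nb)) return(0)
    sum(vapply(nb, probe, 0, step = step + 1)) / length(nb)
  }
  probe(source, 1)
}

undirected_adj <- function(triples, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(triples$head, triples$tail))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    adj[[v]] <- setdiff(unique(c(triples$tail[triples$head == v],
                                 triples$head[triples$tail == v])), v)
  }
  adj
}
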