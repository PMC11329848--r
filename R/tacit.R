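# Tacit ("entity"-level) completion: level-wise Apriori over medical-record
# transactions, syndrome-antecedent / symptom-consequent rules scored by
# support, confidence and lift = confidence / support(consequent); rules
# with lift above threshold convert to Manifest triples.

itemset_key <- function(items) paste(sort(items), collapse = "\037")

#' Frequent itemsets by the Apriori algorithm
#'
#' Level-wise generation with Apriori pruning: a k-itemset is a candidate
#' only if every (k-1)-subset is frequent. Support of an itemset is the
#' proportion of transactions containing it.
#'
#' @param transactions list of character vectors (one record per element).
#' @param min_support minimum support in `(0, 1]`; the conventional default
#'   for this mining task is 0.10.
#' @return Data frame with list column `items` and column `support`,
#'   covering every itemset with support `>= min_support`, ordered by
#'   itemset size then support descending.
#' @export
apriori_frequent_itemsets <- function(transactions, min_support = 0.10) {
  if (!length(transactions)) stop("usage error: empty transaction list")
  stopifnot(min_support > 0, min_support <= 1)
  n <- length(transactions)
  transactions <- lapply(transactions, unique)
  counts <- table(unlist(transactions))
  items <- sort(names(counts)[counts / n >= min_support])
  sets <- list()
  supports <- numeric()
  if (length(items)) {
    # membership matrix over frequent singletons only
    M <- vapply(items, function(it)
      vapply(transactions, function(tx) it %in% tx, TRUE),
      logical(n))
    if (n == 1) M <- matrix(M, nrow = 1, dimnames = list(NULL, items))
    level <- lapply(items, identity)  # frequent singletons
    for (it in items) {
      sets[[length(sets) + 1]] <- it
      supports <- c(supports, sum(M[, it]) / n)
    }
    freq_keys <- vapply(level, itemset_key, "")
    while (length(level) >= 2) {
      # join step: pairs sharing all but the last item
      cand <- list()
      prefix <- vapply(level, function(s)
        paste(s[-length(s)], collapse = "\037"), "")
      for (p in unique(prefix)) {
        grp <- level[prefix == p]
        lasts <- sort(vapply(grp, function(s) s[length(s)], ""))
        if (length(lasts) >= 2) {
          for (i in seq_len(length(lasts) - 1)) {
            for (j in (i + 1):length(lasts)) {
              cand[[length(cand) + 1]] <-
                c(grp[[1]][-length(grp[[1]])], lasts[i], lasts[j])
            }
          }
        }
      }
      if (!length(cand)) break
      k <- length(cand[[1]])
      # prune step: all (k-1)-subsets must be frequent
      cand <- Filter(function(s) {
        all(vapply(seq_along(s), function(d) itemset_key(s[-d]), "") %in%
              freq_keys)
      }, cand)
      if (!length(cand)) break
      sup <- vapply(cand, function(s) sum(rowSums(M[, s, drop = FALSE]) == k),
                    0) / n
      keep <- sup >= min_support
      level <- cand[keep]
      if (length(level)) {
        sets <- c(sets, level)
        supports <- c(supports, sup[keep])
        freq_keys <- c(freq_keys, vapply(level, itemset_key, ""))
      } else break
    }
  }
  out <- data.frame(support = supports)
  out$items <- sets
  out <- out[order(lengths(out$items), -out$support,
                   vapply(out$items, itemset_key, "")), c("items", "support")]
  rownames(out) <- NULL
  out
}

itemset_support <- function(frequent, items) {
  keys <- vapply(frequent$items, itemset_key, "")
  i <- match(itemset_key(items), keys)
  if (is.na(i)) NA_real_ else frequent$support[i]
}

#' Derive association rules from frequent itemsets
#'
#' Emits rules `X -> Y` with `X` a single antecedent-typed item and `Y` a
#' single consequent-typed item, where the pair itemset is frequent.
#' `confidence = support(X u Y) / support(X)` and
#' `lift = confidence / support(Y)`. Rules are sorted by lift descending,
#' ties broken by support descending then labels ascending.
#'
#' @param frequent output of [apriori_frequent_itemsets()].
#' @param antecedent_items character vector of labels eligible as
#'   antecedents (e.g. syndrome labels).
#' @param consequent_items labels eligible as consequents (symptom labels).
#' @return Data frame with columns `antecedent`, `consequent`, `support`,
#'   `confidence`, `lift`.
#' @export
derive_rules <- function(frequent, antecedent_items, consequent_items) {
  empty <- data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE)
  pairs <- frequent[lengths(frequent$items) == 2, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  out <- empty
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$items[[i]]
    for (ord in list(s, rev(s))) {
      x <- ord[1]; y <- ord[2]
      if (!(x %in% antecedent_items) || !(y %in% consequent_items)) next
      sx <- itemset_support(frequent, x)
      sy <- itemset_support(frequent, y)
      if (is.na(sx) || sx == 0) next
      conf <- pairs$support[i] / sx
      out <- rbind(out, data.frame(
        antecedent = x, consequent = y, support = pairs$support[i],
        confidence = conf, lift = conf / sy, stringsAsFactors = FALSE))
    }
  }
  out <- out[order(-out$lift, -out$support, out$antecedent, out$consequent), ]
  rownames(out) <- NULL
  out
}

#' Select rules by lift and convert them to triples
#'
#' Keeps rules with `lift > lift_threshold` (default 1, i.e. positively
#' associated pairs) and converts each to a
#' `(antecedent, relation, consequent)` triple with provenance
#' `association_rule`. Rules already present as triples of `kg` are dropped.
#'
#' @param rules output of [derive_rules()].
#' @param lift_threshold keep rules with lift strictly above this.
#' @param relation relation name for the emitted triples (default
#'   `"Manifest"`).
#' @param kg optional `kg` used to drop duplicates of existing triples.
#' @return Data frame of new triples.
#' @export
select_and_convert <- function(rules, lift_threshold = 1,
                               relation = "Manifest", kg = NULL) {
  keep <- rules[rules$lift > lift_threshold, , drop = FALSE]
  out <- data.frame(head = keep$antecedent, relation = relation,
                    tail = keep$consequent, provenance = "association_rule",
                    stringsAsFactors = FALSE)
  if (!is.null(kg) && nrow(out)) {
    out <- out[!(triple_key(out) %in% triple_key(kg$triples)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write association rules as TSV
#'
#' Columns: antecedent, consequent, support, confidence, lift.
#'
#' @param rules output of [derive_rules()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
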