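# Usability evaluation: knowledge-graph embeddings (TransE, RotatE,
# DistMult, ComplEx) trained with tail-corruption negative sampling and
# margin ranking loss by per-triple stochastic gradient descent, evaluated
# by tail-entity ranking: MR, MRR, Hits@{1,3,10} on a held-out split.
#
# Real-valued storage: for the complex models an even dimension d holds
# d/2 complex coordinates as (real block, imaginary block). RotatE relation
# parameters are phases, so relation moduli are exactly 1 by construction.

KGE_MODELS <- c("TransE", "RotatE", "DistMult", "ComplEx")

#' Embedding training configuration
#'
#' @param model one of `"TransE"`, `"RotatE"`, `"DistMult"`, `"ComplEx"`.
#' @param dimension embedding dimension (must be even for RotatE/ComplEx;
#'   counts real numbers per entity, i.e. d/2 complex coordinates).
#' @param margin margin of the ranking loss.
#' @param learning_rate SGD step size.
#' @param epochs passes over the training triples.
#' @param negatives_per_positive corrupted tails per positive per epoch.
#' @param loss `"margin"` (default, max(0, margin - s_pos + s_neg)) or
#'   `"logistic"`.
#' @param seed integer seed (initialization and negative sampling).
#' @return List of class `kge_config`.
#' @export
embedding_config <- function(model = "TransE", dimension = 100, margin = 1,
                             learning_rate = 0.01, epochs = 200,
                             negatives_per_positive = 1,
                             loss = c("margin", "logistic"), seed = 1L) {
  model <- match.arg(model, KGE_MODELS)
  loss <- match.arg(loss)
  stopifnot(dimension >= 2, margin > 0, learning_rate > 0, epochs >= 0,
            negatives_per_positive >= 1)
  if (model %in% c("RotatE", "ComplEx") && dimension %% 2 != 0) {
    stop("dimension must be even for ", model)
  }
  structure(list(model = model, dimension = as.integer(dimension),
                 margin = margin, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 loss = loss, seed = as.integer(seed)),
            class = "kge_config")
}

#' Split triples into train and validation sets
#'
#' Uniform seeded shuffle; the first `round(ratio * n)` triples form the
#' training set. Validation triples whose head, tail or relation does not
#' appear in the training set are moved to training (logged), so every
#' validation entity and relation is embeddable.
#'
#' @param kg a `kg` (or a triple data frame) with at least 10 triples.
#' @param ratio training fraction in `(0, 1)` (default 0.7, the 7:3 split).
#' @param seed integer seed.
#' @return List with data frames `train` and `validation`.
#' @export
split_triples <- function(kg, ratio = 0.7, seed = 1L) {
  tr <- if (inherits(kg, "kg")) kg$triples else as.data.frame(kg)
  if (nrow(tr) < 10) stop("need at least 10 triples to split")
  if (ratio <= 0 || ratio >= 1) stop("usage error: ratio outside (0, 1)")
  with_seed(seed, {
    ord <- sample(nrow(tr))
    n_train <- round(ratio * nrow(tr))
    train <- tr[ord[seq_len(n_train)], , drop = FALSE]
    valid <- tr[ord[-seq_len(n_train)], , drop = FALSE]
    bad <- !(valid$head %in% c(train$head, train$tail)) |
           !(valid$tail %in% c(train$head, train$tail)) |
           !(valid$relation %in% train$relation)
    # entities appearing earlier in the relocation can unlock later triples,
    # so iterate until stable
    while (any(bad)) {
      train <- rbind(train, valid[bad, , drop = FALSE])
      valid <- valid[!bad, , drop = FALSE]
      message(sum(bad), " validation triple(s) moved to train for coverage")
      bad <- !(valid$head %in% c(train$head, train$tail)) |
             !(valid$tail %in% c(train$head, train$tail)) |
             !(valid$relation %in% train$relation)
    }
    rownames(train) <- rownames(valid) <- NULL
    list(train = train, validation = valid)
  })
}

#' Corrupt the tail of a triple
#'
#' Replaces the tail with a uniform draw from `pool` different from the
#' original tail; corruptions that are known true triples are resampled up
#' to `max_retry` times, then accepted with a warning.
#'
#' @param triple list or 1-row data frame with `head`, `relation`, `tail`.
#' @param pool character vector of candidate entities (>= 2).
#' @param known_keys optional character vector of `triple_key`s to avoid.
#' @param max_retry bounded resampling attempts.
#' @return The corrupted triple as a list.
#' @export
negative_sample <- function(triple, pool, known_keys = character(),
                            max_retry = 10) {
  stopifnot(length(pool) >= 2)
  for (i in seq_len(max_retry)) {
    t_new <- sample(pool, 1)
    if (t_new == triple$tail) next
    key <- paste(triple$head, triple$relation, t_new, sep = "\r")
    if (!(key %in% known_keys)) {
      return(list(head = triple$head, relation = triple$relation,
                  tail = t_new))
    }
  }
  warning("negative_sample: retry budget exhausted; accepting a known triple")
  list(head = triple$head, relation = triple$relation, tail = t_new)
}

init_model <- function(entities, relations, config) {
  d <- config$dimension
  E <- matrix(stats::runif(length(entities) * d, -6 / sqrt(d), 6 / sqrt(d)),
              length(entities), d, dimnames = list(entities, NULL))
  if (config$model == "RotatE") {
    R <- matrix(stats::runif(length(relations) * d / 2, -pi, pi),
                length(relations), d / 2, dimnames = list(relations, NULL))
  } else {
    R <- matrix(stats::runif(length(relations) * d, -6 / sqrt(d), 6 / sqrt(d)),
                length(relations), d, dimnames = list(relations, NULL))
  }
  structure(list(model = config$model, dimension = d, E = E, R = R,
                 entities = entities, relations = relations),
            class = "kge_model")
}

#' @export
print.kge_model <- function(x, ...) {
  cat("<kge_model> ", x$model, ", d=", x$dimension, ", ",
      length(x$entities), " entities, ", length(x$relations),
      " relations\n", sep = "")
  invisible(x)
}

split_complex <- function(v) {
  k <- length(v) / 2
  list(re = v[seq_len(k)], im = v[k + seq_len(k)])
}

#' Score a triple under an embedding model
#'
#' Higher is more plausible. TransE: `-||h + r - t||_2`. RotatE:
#' `-||h o r - t||_2` with elementwise complex product and unit-modulus
#' relation (phase parametrization). DistMult: `sum_i h_i r_i t_i`.
#' ComplEx: `Re(sum_i h_i r_i conj(t_i))`.
#'
#' @param model a `kge_model`.
#' @param h,r,t head entity id, relation name, tail entity id.
#' @return Numeric score.
#' @export
score_triple <- function(model, h, r, t) {
  if (!(h %in% model$entities) || !(t %in% model$entities) ||
      !(r %in% model$relations)) {
    stop("lookup error: id not embedded")
  }
  unname(drop(score_tails(model, h, r, model$E[t, , drop = FALSE])))
}

# vectorized scores of one (h, r) against a tail matrix Tm (rows = tails)
score_tails <- function(model, h, r, Tm) {
  hv <- model$E[h, ]
  rv <- model$R[r, ]
  switch(model$model,
    TransE = {
      v <- sweep(-Tm, 2, hv + rv, "+")
      -sqrt(rowSums(v * v))
    },
    DistMult = drop(Tm %*% (hv * rv)),
    ComplEx = {
      hc <- split_complex(hv); rc <- split_complex(rv)
      ur <- hc$re * rc$re - hc$im * rc$im
      ui <- hc$re * rc$im + hc$im * rc$re
      k <- length(ur)
      drop(Tm[, seq_len(k), drop = FALSE] %*% ur +
           Tm[, k + seq_len(k), drop = FALSE] %*% ui)
    },
    RotatE = {
      hc <- split_complex(hv)
      ur <- hc$re * cos(rv) - hc$im * sin(rv)
      ui <- hc$re * sin(rv) + hc$im * cos(rv)
      k <- length(ur)
      vr <- sweep(-Tm[, seq_len(k), drop = FALSE], 2, ur, "+")
      vi <- sweep(-Tm[, k + seq_len(k), drop = FALSE], 2, ui, "+")
      -sqrt(rowSums(vr * vr) + rowSums(vi * vi))
    })
}

# gradient of score wrt (h, r, t) at a single triple; returns list(dh, dr, dt)
score_grad <- function(model, hi, ri, ti) {
  score_and_grad(model$model, model$E[hi, ], model$R[ri, ],
                 model$E[ti, ])[c("dh", "dr", "dt")]
}

# score plus its gradient in one pass (the norm-based models share the
# residual vector between the two)
score_and_grad <- function(tag, hv, rv, tv) {
  eps <- 1e-12
  k <- length(hv) %/% 2
  i1 <- seq_len(k); i2 <- k + i1
  switch(tag,
    TransE = {
      v <- hv + rv - tv
      nv <- sqrt(sum(v * v)) + eps
      g <- -v / nv
      list(s = -nv, dh = g, dr = g, dt = -g)
    },
    DistMult = list(s = sum(hv * rv * tv), dh = rv * tv, dr = hv * tv,
                    dt = hv * rv),
    ComplEx = {
      a <- hv[i1]; b <- hv[i2]; cc <- rv[i1]; d <- rv[i2]
      e <- tv[i1]; f <- tv[i2]
      list(s = sum((a * cc - b * d) * e + (a * d + b * cc) * f),
           dh = c(cc * e + d * f, -d * e + cc * f),
           dr = c(a * e + b * f, -b * e + a * f),
           dt = c(a * cc - b * d, a * d + b * cc))
    },
    RotatE = {
      a <- hv[i1]; b <- hv[i2]
      cs <- cos(rv); sn <- sin(rv)
      vr <- a * cs - b * sn - tv[i1]
      vi <- a * sn + b * cs - tv[i2]
      nv <- sqrt(sum(vr * vr + vi * vi)) + eps
      list(s = -nv,
           dh = c(-(vr * cs + vi * sn), -(-vr * sn + vi * cs)) / nv,
           dr = -(vr * (-a * sn - b * cs) + vi * (a * cs - b * sn)) / nv,
           dt = c(vr, vi) / nv)
    })
}

#' Train a knowledge-graph embedding model
#'
#' Per-triple stochastic gradient descent on the margin ranking loss
#' `max(0, margin - score(pos) + score(neg))` (or the logistic alternative),
#' with one fresh tail-corrupted negative per positive per epoch. Entity
#' vectors are renormalized to unit L2 norm after every epoch; RotatE
#' relation parameters are phases, so relation moduli are exactly 1
#' throughout. Deterministic given the config seed. With `epochs = 0` the
#' seeded random initialization is returned unchanged.
#'
#' @param train data frame of training triples.
#' @param config an [embedding_config()].
#' @param entities optional entity universe (default: entities of `train`).
#' @return A `kge_model` with attribute `"loss_trajectory"` (mean epoch
#'   loss).
#' @export
train_embeddings <- function(train, config, entities = NULL) {
  stopifnot(inherits(config, "kge_config"), nrow(train) >= 1)
  if (is.null(entities)) entities <- sort(unique(c(train$head, train$tail)))
  relations <- sort(unique(train$relation))
  known <- triple_key(train)
  with_seed(config$seed, {
    model <- init_model(entities, relations, config)
    lr <- config$learning_rate
    tag <- config$model
    traj <- numeric(config$epochs)
    hi <- match(train$head, entities)
    ri <- match(train$relation, relations)
    ti <- match(train$tail, entities)
    known_env <- new.env(parent = emptyenv(), size = 2L * length(known))
    for (key in known) known_env[[key]] <- TRUE
    n_ent <- length(entities)
    E <- model$E; R <- model$R
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nrow(train))
      ep_loss <- 0
      for (i in ord) {
        h <- hi[i]; r <- ri[i]; t <- ti[i]
        for (negrep in seq_len(config$negatives_per_positive)) {
          # tail corruption with bounded resampling of known-true triples
          tn <- t
          for (try in 1:10) {
            tn <- sample.int(n_ent, 1)
            if (tn == t) next
            if (is.null(known_env[[paste(train$head[i], train$relation[i],
                                         entities[tn], sep = "\r")]])) break
          }
          if (tn == t) next
          gp <- score_and_grad(tag, E[h, ], R[r, ], E[t, ])
          gn <- score_and_grad(tag, E[h, ], R[r, ], E[tn, ])
          if (config$loss == "margin") {
            loss <- config$margin - gp$s + gn$s
            if (!is.finite(loss)) stop("non-finite loss at epoch ", ep)
            if (loss <= 0) next
            ep_loss <- ep_loss + loss
            w_pos <- 1; w_neg <- 1
          } else {
            ep_loss <- ep_loss + log1p(exp(-gp$s)) + log1p(exp(gn$s))
            w_pos <- 1 / (1 + exp(gp$s))         # sigma(-s_pos)
            w_neg <- 1 / (1 + exp(-gn$s))        # sigma(s_neg)
          }
          # ascend the positive score, descend the negative score
          E[h, ] <- E[h, ] + lr * (w_pos * gp$dh - w_neg * gn$dh)
          E[t, ] <- E[t, ] + lr * w_pos * gp$dt
          R[r, ] <- R[r, ] + lr * (w_pos * gp$dr - w_neg * gn$dr)
          E[tn, ] <- E[tn, ] - lr * w_neg * gn$dt
        }
      }
      nrm <- sqrt(rowSums(E^2))
      nrm[nrm < 1e-12] <- 1
      E <- E / nrm
      if (tag == "RotatE") {
        R <- ((R + pi) %% (2 * pi)) - pi  # keep phases in (-pi, pi]
      }
      traj[ep] <- ep_loss / nrow(train)
    }
    model$E <- E; model$R <- R
    attr(model, "loss_trajectory") <- traj
    model
  })
}

#' Rank the true tail among all candidate tails
#'
#' Scores every candidate tail for `(head, relation, ?)`; the rank is 1 plus
#' the number of candidates scoring strictly better than the true tail
#' (optimistic tie handling). Raw ranking by default; with
#' `filter_known` the supplied known-true tails (other than the evaluated
#' one) are excluded from the candidate set.
#'
#' @param model a `kge_model`.
#' @param triple list/row with `head`, `relation`, `tail`.
#' @param entities candidate tail pool (default: all embedded entities).
#' @param filter_known optional character vector of known-true tails for
#'   this (head, relation) to exclude (filtered ranking).
#' @return Integer rank >= 1.
#' @export
rank_tail <- function(model, triple, entities = model$entities,
                      filter_known = NULL) {
  if (!is.null(filter_known)) {
    entities <- setdiff(entities, setdiff(filter_known, triple$tail))
  }
  if (!(triple$tail %in% entities)) entities <- c(entities, triple$tail)
  sc <- score_tails(model, triple$head, triple$relation,
                    model$E[entities, , drop = FALSE])
  s_true <- sc[match(triple$tail, entities)]
  1L + sum(sc > s_true)
}

#' Tail-ranking metrics: MR, MRR, Hits@{1,3,10}
#'
#' `MR = mean(rank_i)`, `MRR = mean(1/rank_i)`,
#' `Hits@N = mean(rank_i <= N)`, reported to 4 decimals.
#'
#' @param model a `kge_model`.
#' @param validation data frame of evaluation triples.
#' @param entities candidate tail pool (default: all embedded entities).
#' @param filtered exclude other known-true tails (from `known`) when
#'   ranking?
#' @param known data frame of known-true triples for filtering (default:
#'   `validation` itself).
#' @return List of class `kg_ranking_metrics`: `mr`, `mrr`, `hits1`,
#'   `hits3`, `hits10`, `ranks`.
#' @export
ranking_metrics <- function(model, validation, entities = model$entities,
                            filtered = FALSE, known = validation) {
  stopifnot(nrow(validation) >= 1)
  known_tails <- if (filtered) {
    split(known$tail, paste(known$head, known$relation, sep = "\r"))
  } else NULL
  ranks <- vapply(seq_len(nrow(validation)), function(i) {
    tri <- list(head = validation$head[i], relation = validation$relation[i],
                tail = validation$tail[i])
    fk <- if (filtered)
      known_tails[[paste(tri$head, tri$relation, sep = "\r")]] else NULL
    rank_tail(model, tri, entities, fk)
  }, 1L)
  structure(list(mr = round_half_up(mean(ranks)),
                 mrr = round_half_up(mean(1 / ranks)),
                 hits1 = round_half_up(mean(ranks <= 1)),
                 hits3 = round_half_up(mean(ranks <= 3)),
                 hits10 = round_half_up(mean(ranks <= 10)),
                 ranks = ranks),
            class = "kg_ranking_metrics")
}

#' @export
print.kg_ranking_metrics <- function(x, ...) {
  cat(sprintf("MRR %.4f | MR %.4f | H@1 %.4f | H@3 %.4f | H@10 %.4f\n",
              x$mrr, x$mr, x$hits1, x$hits3, x$hits10))
  invisible(x)
}

#' Train and evaluate all four embedding models on one graph
#'
#' Convenience wrapper: 7:3 split, one model per tag, tail-ranking metrics
#' on the validation set.
#'
#' @param kg a `kg`.
#' @param models subset of `c("TransE", "RotatE", "DistMult", "ComplEx")`.
#' @param dimension,margin,learning_rate,epochs passed to
#'   [embedding_config()].
#' @param seed integer seed (split and training).
#' @return Named list of `kg_ranking_metrics`.
#' @export
usability_report <- function(kg, models = KGE_MODELS, dimension = 32,
                             margin = 1, learning_rate = 0.05, epochs = 50,
                             seed = 1L) {
  sp <- split_triples(kg, 0.7, seed)
  ents <- sort(unique(c(kg$triples$head, kg$triples$tail)))
  out <- lapply(models, function(m) {
    cfg <- embedding_config(model = m, dimension = dimension,
                            margin = margin, learning_rate = learning_rate,
                            epochs = epochs, seed = seed)
    fit <- train_embeddings(sp$train, cfg, entities = ents)
    ranking_metrics(fit, sp$validation)
  })
  stats::setNames(out, models)
}
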