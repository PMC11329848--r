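test_that("split_triples is a seeded 7:3 partition with coverage repair", {
  gen <- generate_kg(small_gen_config(seed = 3))
  kg <- gen$kg
  sp <- suppressMessages(split_triples(kg, 0.7, 42))
  expect_equal(nrow(sp$train) + nrow(sp$validation), nrow(kg$triples))
  expect_gte(nrow(sp$train), round(0.7 * nrow(kg$triples)))
  # identical seed, identical split
  sp2 <- suppressMessages(split_triples(kg, 0.7, 42))
  expect_identical(sp, sp2)
  # every validation entity and relation occurs in train
  ents <- c(sp$train$head, sp$train$tail)
  expect_true(all(sp$validation$head %in% ents))
  expect_true(all(sp$validation$tail %in% ents))
  expect_true(all(sp$validation$relation %in% sp$train$relation))
  expect_error(split_triples(kg, 1.2, 1), "ratio")
  # 10 triples at 7:3 -> 7 train, 3 validation (before coverage repair)
  tiny <- kg$triples[1:10, ]
  sp10 <- suppressMessages(split_triples(tiny, 0.7, 1))
  expect_equal(nrow(sp10$train) + nrow(sp10$validation), 10)
  expect_gte(nrow(sp10$train), 7)
})

test_that("score functions match their algebraic definitions", {
  ents <- c("a", "b"); rels <- c("r")
  mk <- function(model, E, R) {
    structure(list(model = model, dimension = ncol(E), E = E, R = R,
                   entities = ents, relations = rels),
              class = "kge_model")
  }
  E0 <- matrix(0, 2, 4, dimnames = list(ents, NULL))
  R0 <- matrix(0, 1, 4, dimnames = list(rels, NULL))
  # TransE with h = r = t = 0 scores 0 (its maximum)
  expect_equal(score_triple(mk("TransE", E0, R0), "a", "r", "b"), 0)

  # RotatE identity rotation with h = t scores 0
  set.seed(1)
  E1 <- matrix(stats::rnorm(8), 2, 4, dimnames = list(ents, NULL))
  E1["b", ] <- E1["a", ]
  Rph <- matrix(0, 1, 2, dimnames = list(rels, NULL))  # phase 0
  expect_equal(score_triple(mk("RotatE", E1, Rph), "a", "r", "b"), 0)

  # ComplEx with all-real embeddings equals DistMult on the same vectors
  E2 <- matrix(stats::rnorm(8), 2, 4, dimnames = list(ents, NULL))
  R2 <- matrix(stats::rnorm(4), 1, 4, dimnames = list(rels, NULL))
  E2[, 3:4] <- 0; R2[, 3:4] <- 0  # zero imaginary blocks
  cx <- score_triple(mk("ComplEx", E2, R2), "a", "r", "b")
  Ed <- E2[, 1:2, drop = FALSE]; Rd <- R2[, 1:2, drop = FALSE]
  dm <- score_triple(mk("DistMult", Ed, Rd), "a", "r", "b")
  expect_equal(cx, dm)

  # TransE score agrees with the explicit norm formula on random vectors
  m <- mk("TransE", E2, R2)
  expect_equal(score_triple(m, "a", "r", "b"),
               -sqrt(sum((E2["a", ] + R2[1, ] - E2["b", ])^2)))
  expect_error(score_triple(m, "zz", "r", "b"), "lookup error")
})

test_that("analytic score gradients match numerical differentiation", {
  set.seed(7)
  d <- 6
  hv <- stats::rnorm(d); rv <- stats::rnorm(d); tv <- stats::rnorm(d)
  for (tag in c("TransE", "DistMult", "ComplEx")) {
    g <- kgceval:::score_and_grad(tag, hv, rv, tv)
    num <- function(f, x) {
      vapply(seq_along(x), function(i) {
        e <- rep(0, length(x)); e[i] <- 1e-6
        (f(x + e) - f(x - e)) / 2e-6
      }, 0)
    }
    expect_equal(g$dh, num(function(h)
      kgceval:::score_and_grad(tag, h, rv, tv)$s, hv), tolerance = 1e-5)
    expect_equal(g$dt, num(function(t)
      kgceval:::score_and_grad(tag, hv, rv, t)$s, tv), tolerance = 1e-5)
  }
  # RotatE: phases have half the dimension
  ph <- stats::rnorm(d / 2)
  g <- kgceval:::score_and_grad("RotatE", hv, ph, tv)
  e <- function(i, n) { v <- rep(0, n); v[i] <- 1e-6; v }
  num_r <- vapply(seq_len(d / 2), function(i)
    (kgceval:::score_and_grad("RotatE", hv, ph + e(i, d / 2), tv)$s -
     kgceval:::score_and_grad("RotatE", hv, ph - e(i, d / 2), tv)$s) / 2e-6,
    0)
  expect_equal(g$dr, num_r, tolerance = 1e-5)
})

test_that("negative sampling corrupts only the tail, uniformly", {
  tri <- list(head = "h", relation = "r", tail = "a")
  # forced outcome with a 2-entity pool
  set.seed(1)
  out <- negative_sample(tri, c("a", "b"))
  expect_equal(out$tail, "b")
  expect_equal(out$head, "h"); expect_equal(out$relation, "r")

  # chi-square uniformity over a 10-entity pool
  pool <- letters[1:10]
  set.seed(2)
  draws <- replicate(10000, negative_sample(tri, pool)$tail)
  tab <- table(factor(draws, levels = setdiff(pool, "a")))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
  expect_false("a" %in% names(tab)[tab > 0])
})

test_that("training separates a toy fixture and is deterministic", {
  train <- data.frame(head = c("a", "c"), relation = "r",
                      tail = c("b", "d"), stringsAsFactors = FALSE)
  cfg <- embedding_config("TransE", dimension = 8, epochs = 150,
                          learning_rate = 0.1, margin = 1, seed = 3)
  fit <- train_embeddings(train, cfg)
  s_pos <- score_triple(fit, "a", "r", "b")
  s_neg <- score_triple(fit, "a", "r", "d")
  expect_gt(s_pos, s_neg)
  # determinism
  fit2 <- train_embeddings(train, cfg)
  expect_identical(fit$E, fit2$E)
  # epochs = 0 returns the seeded initialization
  cfg0 <- embedding_config("TransE", dimension = 8, epochs = 0, seed = 3)
  init1 <- train_embeddings(train, cfg0)
  init2 <- train_embeddings(train, cfg0)
  expect_identical(init1$E, init2$E)
  expect_equal(length(attr(init1, "loss_trajectory")), 0)
  # loss trajectory decreases on epoch means (smoke fixture)
  traj <- attr(fit, "loss_trajectory")
  expect_lt(mean(utils::tail(traj, 10)), mean(utils::head(traj, 10)))
  # odd dimension rejected for complex models
  expect_error(embedding_config("RotatE", dimension = 7), "even")
})

test_that("rank_tail is the optimistic rank and matches a full argsort", {
  set.seed(5)
  ents <- sprintf("t%02d", 1:20)
  E <- matrix(stats::rnorm(20 * 6), 20, 6, dimnames = list(ents, NULL))
  R <- matrix(stats::rnorm(6), 1, 6, dimnames = list("r", NULL))
  m <- structure(list(model = "DistMult", dimension = 6, E = E, R = R,
                      entities = ents, relations = "r"),
                 class = "kge_model")
  sc <- sapply(ents, function(t) score_triple(m, "t01", "r", t))
  for (t in ents[c(1, 5, 19)]) {
    want <- 1L + sum(sc > sc[[t]])
    expect_equal(rank_tail(m, list(head = "t01", relation = "r", tail = t)),
                 want)
  }
  # filtered mode removes known-true competitors
  best <- names(which.max(sc))
  worst <- names(which.min(sc))
  r_raw <- rank_tail(m, list(head = "t01", relation = "r", tail = worst))
  r_fil <- rank_tail(m, list(head = "t01", relation = "r", tail = worst),
                     filter_known = c(best, worst))
  expect_equal(r_fil, r_raw - 1L)
})

test_that("ranking metrics: closed form, identities, random baseline", {
  # engineered tail scores: DistMult on 1 effective dimension ranks tails
  # by their embedding value, so the three validation tails sit at ranks
  # 1, 2, 4 by construction
  ents <- c("a", "b", "c", "d", "e")
  E <- matrix(0, 5, 2, dimnames = list(ents, NULL))
  E[, 1] <- c(1, 5, 4, 3, 2)  # a, b, c, d, e
  m <- structure(list(model = "DistMult", dimension = 2, E = E,
                      R = matrix(c(1, 0), 1, 2, dimnames = list("r", NULL)),
                      entities = ents, relations = "r"),
                 class = "kge_model")
  valid3 <- data.frame(head = "a", relation = "r", tail = c("b", "c", "e"),
                       stringsAsFactors = FALSE)
  mm <- ranking_metrics(m, valid3)
  expect_equal(mm$ranks, c(1L, 2L, 4L))
  expect_equal(mm$mr, 2.3333)
  expect_equal(mm$mrr, 0.5833)
  expect_equal(mm$hits1, 0.3333)
  expect_equal(mm$hits3, 0.6667)
  expect_equal(mm$hits10, 1)

  # all-ties embeddings: every rank is 1 (optimistic), metrics all 1
  m0 <- m; m0$E[] <- 0
  valid <- data.frame(head = "a", relation = "r", tail = c("b", "c"),
                      stringsAsFactors = FALSE)
  mm1 <- ranking_metrics(m0, valid)
  expect_equal(c(mm1$mr, mm1$mrr, mm1$hits1, mm1$hits10), c(1, 1, 1, 1))

  # random embeddings give MR near (n+1)/2 and the hits chain holds
  set.seed(11)
  n <- 40
  ents_n <- sprintf("e%02d", 1:n)
  En <- matrix(stats::rnorm(n * 8), n, 8, dimnames = list(ents_n, NULL))
  mr_vals <- replicate(30, {
    Em <- matrix(stats::rnorm(n * 8), n, 8, dimnames = list(ents_n, NULL))
    mdl <- structure(list(model = "DistMult", dimension = 8, E = Em,
                          R = matrix(stats::rnorm(8), 1, 8,
                                     dimnames = list("r", NULL)),
                          entities = ents_n, relations = "r"),
                     class = "kge_model")
    vl <- data.frame(head = sample(ents_n, 20, TRUE), relation = "r",
                     tail = sample(ents_n, 20, TRUE),
                     stringsAsFactors = FALSE)
    met <- ranking_metrics(mdl, vl)
    expect_lte(met$hits1, met$hits3)
    expect_lte(met$hits3, met$hits10)
    expect_lte(met$mrr, 1)
    expect_gte(met$mrr, 1 / met$mr)  # Jensen
    met$mr
  })
  se <- sqrt(((n^2 - 1) / 12) / (30 * 20))
  expect_lt(abs(mean(mr_vals) - (n + 1) / 2), 4 * se)
})

test_that("symmetry-capable models beat TransE on held-out reverses", {
  mods <- c("TransE", "RotatE", "DistMult", "ComplEx")
  mrr <- sapply(mods, function(m) {
    mean(sapply(1:5, function(s) {
      fx <- pattern_fixture(seed = s)
      cfg <- embedding_config(m, dimension = 16, epochs = 60,
                              learning_rate = 0.05, seed = 50 + s)
      fit <- train_embeddings(fx$train, cfg, entities = fx$entities)
      ranking_metrics(fit, fx$valid_sym)$mrr
    }))
  })
  expect_gt(mrr[["RotatE"]], mrr[["TransE"]])
  expect_gt(mrr[["ComplEx"]], mrr[["TransE"]])
  expect_gt(mrr[["DistMult"]], mrr[["TransE"]])
})
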