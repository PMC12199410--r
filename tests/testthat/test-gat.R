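hn <- asNamespace("herbnet")

path3 <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A
}

test_that("attention coefficients are a softmax over the neighborhood", {
  # isolated node: self-loop only, attention mass 1
  A <- matrix(0L, 2, 2); A[1, 2] <- A[2, 1] <- 0L
  edges <- hn$gat_edges(A)
  H <- matrix(rnorm(4), 2)
  W <- matrix(rnorm(4), 2)
  a <- rnorm(4)
  at <- attention_coefficients(H, edges, W, a)
  expect_equal(unname(at$alpha), c(1, 1))

  # two neighbors with identical features split attention evenly
  A3 <- path3()
  H3 <- matrix(c(1, 0.5, 1,  2, -1, 2), 3)   # nodes 1 and 3 identical
  e3 <- hn$gat_edges(A3)
  at3 <- attention_coefficients(H3, e3, W, a)
  a2 <- at3$alpha[e3$i == 2]
  j2 <- e3$j[e3$i == 2]
  expect_equal(a2[j2 == 1], a2[j2 == 3])
  # normalization within every node
  expect_equal(unname(rowsum(at3$alpha, e3$i)[, 1]), rep(1, 3))

  # hand-computed softmax oracle on the 3-node path
  Wh <- H3 %*% W
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  man_e <- sapply(seq_along(e3$i), function(k) {
    lrelu(sum(a[1:2] * Wh[e3$i[k], ]) + sum(a[3:4] * Wh[e3$j[k], ]))
  })
  man_alpha <- unlist(lapply(1:3, function(i) {
    v <- exp(man_e[e3$i == i]); v / sum(v)
  }))
  expect_equal(unname(at3$alpha[order(e3$i, e3$j)]),
               unname(man_alpha), tolerance = 1e-6)

  expect_error(attention_coefficients(H3, e3, W, rnorm(3)), "match")
})

test_that("forward pass has the contracted shape, equivariance and tie-down", {
  set.seed(21)
  n <- 8
  A <- matrix(rbinom(n * n, 1, 0.3), n)
  A <- matrix(as.integer((A + t(A)) > 0), n); diag(A) <- 0L
  X <- matrix(rnorm(n * 5), n)
  cfg <- gat_config(in_dim = 5, hidden_dim = 8, out_dim = 3, heads = 2,
                    dropout = 0, seed = 2)
  params <- hn$gat_init_params(cfg)
  sc <- gat_forward(X, A, params, cfg)
  expect_equal(dim(sc), c(n, 3))

  # zero weights: logits collapse to zero, probabilities to 1/2
  zero <- rapply(params, function(x) x * 0, how = "replace")
  expect_true(all(gat_forward(X, A, zero, cfg) == 0.5))

  # node relabeling permutes outputs identically
  perm <- sample(n)
  sc_p <- gat_forward(X[perm, ], A[perm, perm], params, cfg)
  expect_equal(unname(sc_p), unname(sc[perm, ]), tolerance = 1e-12)

  # evaluation is dropout-free: repeated passes agree exactly
  cfg_d <- gat_config(in_dim = 5, hidden_dim = 8, out_dim = 3, heads = 2,
                      dropout = 0.5, seed = 2)
  expect_identical(gat_forward(X, A, params, cfg_d),
                   gat_forward(X, A, params, cfg_d))
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  n <- 6
  A <- matrix(0L, n, n)
  for (e in list(c(1, 2), c(2, 3), c(4, 5), c(1, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  X <- matrix(rnorm(n * 4), n)
  Y <- matrix(rbinom(n * 3, 1, 0.5), n)
  cfg <- gat_config(in_dim = 4, hidden_dim = 4, out_dim = 3, heads = 2,
                    dropout = 0, seed = 3)
  params <- hn$gat_init_params(cfg)
  edges <- hn$gat_edges(A)
  mask <- c(rep(TRUE, 4), FALSE, FALSE)
  gr <- hn$gat_gradients(X, edges, params, cfg, Y, mask)
  flat <- hn$gat_flatten(params)
  loss_at <- function(fl) {
    fw <- hn$gat_forward_full(X, edges, hn$gat_unflatten(fl, params), cfg)
    hn$bce_masked(fw$logits, Y, mask)$loss
  }
  set.seed(1)
  for (nm in names(flat)) {
    idx <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
    for (i in idx) {
      h <- 1e-5
      up <- flat; up[[nm]][i] <- up[[nm]][i] + h
      dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - h
      expect_equal(gr$grads[[nm]][i], (loss_at(up) - loss_at(dn)) / (2 * h),
                   tolerance = 1e-6)
    }
  }
})

test_that("training optimizes, is seeded, and early loss is non-increasing", {
  d <- fixture("gat_small", function() planted_gat_data(0, n_herbs = 80))
  cfg <- gat_config(in_dim = ncol(d$X), hidden_dim = 16,
                    out_dim = ncol(d$Y), heads = 2, dropout = 0,
                    learning_rate = 0.01, max_epochs = 30, patience = 30,
                    seed = 1)
  m1 <- train_gat(d$X, d$A, d$Y, d$splits, cfg)
  expect_true(all(diff(m1$history$train_loss[1:5]) <= 1e-8))
  m2 <- train_gat(d$X, d$A, d$Y, d$splits, cfg)
  expect_identical(m1$scores, m2$scores)
  expect_equal(unclass(m1$metrics)[1:4], unclass(m2$metrics)[1:4])
  expect_error(train_gat(d$X, d$A, d$Y,
                         list(train = rep(TRUE, nrow(d$X)),
                              val = rep(FALSE, nrow(d$X)),
                              test = rep(FALSE, nrow(d$X))), cfg),
               "split")
})

test_that("herb ranking orders by score with herb-id tie-breaks", {
  sc <- matrix(0.5, 4, 2, dimnames = list(c("H2", "H1", "H4", "H3"), NULL))
  r <- rank_herbs(sc, 1, novel_only = FALSE)
  expect_equal(r$herb_id, c("H1", "H2", "H3", "H4"))

  sc2 <- matrix(c(0.9, 0.1, 0.5, 0.7), 4, 1,
                dimnames = list(paste0("H", 1:4), NULL))
  r2 <- rank_herbs(sc2, 1, known_mask = c(0, 0, 1, 0), top_k = 2)
  expect_equal(r2$herb_id, c("H1", "H4"))   # H3 excluded as known

  big <- matrix(runif(20), 20, 1, dimnames = list(sprintf("H%02d", 1:20),
                                                  NULL))
  expect_equal(nrow(rank_herbs(big, 1, top_k = 15, novel_only = FALSE)), 15)
  expect_error(rank_herbs(sc2, "CVA", categories = c("D1")), "unknown")
})

test_that("ranking prioritizes herbs sharing the disease's planted traits", {
  # hide a third of one disease's planted associations; the model should
  # surface the hidden planted-property herbs among its top novel picks
  d <- fixture("gat_planted_0", function() planted_gat_data(0))
  props <- hn$herb_property_sets(d$herbs)
  j <- 1
  overlap <- vapply(props, function(p)
    sum(d$lab$planted[[j]] %in% p), numeric(1))
  planted_pos <- which(overlap >= 1 & d$Y[, j] == 1)
  hide <- with_seed_test(9, sample(planted_pos, 20))
  Ytr <- d$Y
  Ytr[hide, j] <- 0L
  m <- train_gat(d$X, d$A, Ytr, d$splits, planted_gat_config(d, 0))
  top10 <- rank_herbs(m$scores, j, known_mask = Ytr[, j], top_k = 10)
  idx <- match(top10$herb_id, d$herbs$herb_id)
  expect_gte(mean(overlap[idx] >= 1), 0.5)
})

test_that("baseline models satisfy their contracts", {
  d <- fixture("gat_small", function() planted_gat_data(0, n_herbs = 80))

  # memorization: 1-NN scored on its own training nodes is perfect
  knn <- run_baseline(d$X, d$Y, d$splits, "k-nearest-neighbor", k = 1)
  tr <- d$splits$train
  expect_equal(average_precision(knn$scores[tr, ], d$Y[tr, ]), 1)

  # linearly separable labels: logistic regression near-perfect
  set.seed(6)
  Xs <- matrix(rnorm(200), 50, 4)
  Ys <- cbind(as.integer(Xs[, 1] > 0), as.integer(Xs[, 2] > 0))
  sp <- sample_node_split(50, 3)
  lr <- run_baseline(Xs, Ys, sp, "logistic-regression")
  expect_gte(lr$metrics$roc_auc, 0.9)

  gc <- run_baseline(d$X, d$Y, d$splits, "graph-convolution", A = d$A,
                     seed = 1)
  expect_true(all(gc$scores >= 0 & gc$scores <= 1))
  expect_error(run_baseline(d$X, d$Y, d$splits, "graph-convolution"),
               "requires A")
})

test_that("edge-borne signal favors the GAT over feature-only regression", {
  wins <- 0
  for (s in 0:4) {
    n <- 60
    cfg <- sim_config(n_herbs = n, n_prescriptions = 1500,
                      synergy_blocks = split(1:60, rep(1:6, each = 10)),
                      block_boost = 10, property_homophily = 0, seed = s)
    herbs <- generate_herb_table(cfg)
    A <- build_adjacency(
      count_cooccurrence(generate_prescriptions(cfg, herbs)),
      herbs$herb_id)
    set.seed(s + 77)
    X <- matrix(rnorm(n * 20), n)           # features carry no signal
    Y <- sapply(1:6, function(b) as.integer(rep(1:6, each = 10) == b))
    sp <- sample_node_split(n, s + 50)
    g <- train_gat(X, A, Y, sp,
                   gat_config(in_dim = 20, hidden_dim = 32, out_dim = 6,
                              heads = 4, dropout = 0.1,
                              learning_rate = 0.01, max_epochs = 150,
                              patience = 20, seed = s))
    lr <- run_baseline(X, Y, sp, "logistic-regression")
    if (g$metrics$ap > lr$metrics$ap) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
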