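toy_ppi <- function() {
  igraph::graph_from_data_frame(
    data.frame(a = c("u", "v", "v", "w"),
               b = c("v", "w", "x", "x")), directed = FALSE)
}

test_that("edge weights implement the three transforms", {
  g <- toy_ppi()
  pert <- c(u = 0.4, v = -0.8, w = 0, x = 0)
  B <- build_weighted_ppi(g, pert, "literal-mean-abs")
  ends <- igraph::ends(B, igraph::E(B))
  w_uv <- igraph::E(B)$weight[apply(ends, 1, setequal, c("u", "v"))]
  expect_equal(w_uv, 0.6)

  # all-zero perturbation: every weight 0, every finite distance 0
  B0 <- build_weighted_ppi(g, pert * 0, "literal-mean-abs")
  expect_true(all(igraph::E(B0)$weight == 0))
  expect_equal(shortest_distance(B0, "u", "x"), 0)

  # inverse transform reverses the weight ordering exactly
  pert2 <- c(u = 0.4, v = -0.8, w = 0.1, x = 1.5)
  Bl <- build_weighted_ppi(g, pert2, "literal-mean-abs")
  Bi <- build_weighted_ppi(g, pert2, "inverse")
  expect_equal(rank(igraph::E(Bl)$weight), rank(-igraph::E(Bi)$weight))
  Be <- build_weighted_ppi(g, pert2, "exp-decay")
  expect_equal(rank(igraph::E(Bl)$weight), rank(-igraph::E(Be)$weight))

  expect_error(build_weighted_ppi(g, pert, "nope"))
})

test_that("shortest distances satisfy the Dijkstra contract", {
  g <- toy_ppi()
  pert <- c(u = 0.2, v = 0.4, w = 0.1, x = 0.3)
  B <- build_weighted_ppi(g, pert)
  expect_equal(shortest_distance(B, "u", "u"), 0)
  # single edge: distance equals the edge weight
  expect_equal(shortest_distance(B, "u", "v"), 0.3)
  expect_error(shortest_distance(B, "u", "zz"), "absent")

  # disconnected pair
  g2 <- igraph::add_vertices(B, 1, name = "iso")
  expect_equal(shortest_distance(g2, "u", "iso"), Inf)
})

test_that("distance matrix rows and columns follow the contracts", {
  g <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("g", 1:6)
  pert <- setNames(rep(1, 6), paste0("g", 1:6))  # unit |lfc| -> weight 1
  B <- build_weighted_ppi(g, pert)
  C <- distance_matrix(B, c("g2", "g3"), c("g2", "g4", "g1"))
  expect_equal(C["g2", "g2"], 0)
  # star graph with unit weights: distances equal hop counts
  hops <- igraph::distances(g, weights = NA)
  expect_equal(C["g2", "g4"], hops["g2", "g4"])
  expect_equal(C["g3", "g1"], hops["g3", "g1"])

  gi <- igraph::add_vertices(B, 1, name = "iso")
  Ci <- distance_matrix(gi, c("g2", "g3"), c("g4", "iso"))
  expect_true(all(is.infinite(Ci[, "iso"])))
  expect_error(distance_matrix(B, "absent", "g2"), "empty overlap")
  Cd <- distance_matrix(B, c("g2", "nope"), "g4")
  expect_equal(attr(Cd, "dropped")$rows, "nope")
})

test_that("distances equal exhaustive path enumeration on small graphs", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(3:8, 1)
    W <- matrix(NA_real_, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- runif(1, 0, 2)
    }
    el <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
    if (nrow(el) == 0) next
    g <- igraph::graph_from_data_frame(
      data.frame(a = paste0("n", el[, 1]), b = paste0("n", el[, 2])),
      directed = FALSE,
      vertices = data.frame(name = paste0("n", 1:n)))
    igraph::E(g)$weight <- W[el]
    ij <- sample(n, 2)
    expect_equal(
      shortest_distance(g, paste0("n", ij[1]), paste0("n", ij[2])),
      enum_shortest_path(W, ij[1], ij[2]))
  }
})

test_that("flagging keeps exactly the floor-fraction smallest distances", {
  set.seed(9)
  C <- matrix(runif(100), 10, 10)
  f <- flag_top_fraction(C, 0.05)
  expect_equal(sum(f), 5)
  # full-sort oracle
  expect_setequal(which(f), order(C)[1:5])

  # all-equal matrix: ties resolved in row-then-column order
  Ce <- matrix(1, 10, 10)
  fe <- flag_top_fraction(Ce, 0.05)
  expect_equal(which(fe, arr.ind = TRUE, useNames = FALSE),
               cbind(1L, 1:5))

  # infinite entries are excluded from the denominator
  Ci <- C; Ci[, 1] <- Inf
  fi <- flag_top_fraction(Ci, 0.05)
  expect_equal(sum(fi), floor(0.05 * 90))
  expect_true(all(!fi[, 1]))
  expect_error(flag_top_fraction(matrix(Inf, 2, 2)), "finite")

  pc <- flag_top_fraction(C, 0.2, scope = "per-column")
  expect_equal(unname(colSums(pc)), rep(2, 10))
})

test_that("targets inherit the union of their herbs' theory groups", {
  targets <- data.frame(
    herb = c("h1", "h1", "h2"),
    ingredient = c("i1", "i1", "i2"),
    target = c("t1", "t2", "t1"),
    score = c(900, 800, 750), stringsAsFactors = FALSE)
  theory <- data.frame(
    herb = c("h1", "h2"), qi = c("cold", "warm"),
    flavors = c("pungent", "sweet"), meridians = c("lung", "liver"),
    stringsAsFactors = FALSE)
  gr <- map_targets_to_theory_groups(targets, theory)
  expect_setequal(gr$t1, c("herb:h1", "qi:cold", "flavor:pungent",
                           "meridian:lung", "herb:h2", "qi:warm",
                           "flavor:sweet", "meridian:liver"))
  expect_setequal(gr$t2, c("herb:h1", "qi:cold", "flavor:pungent",
                           "meridian:lung"))

  # score threshold: a 700 score is dropped (strictly above required)
  t2 <- transform(targets, score = c(900, 800, 700))
  gr2 <- map_targets_to_theory_groups(t2, theory)
  expect_false("herb:h2" %in% gr2$t1)

  expect_error(map_targets_to_theory_groups(
    transform(targets, herb = c("h1", "h1", "zz")), theory), "mapping gap")

  # brute-force join oracle on a synthetic fixture
  set.seed(15)
  syn <- data.frame(
    herb = sample(theory$herb, 30, TRUE),
    ingredient = sample(paste0("i", 1:5), 30, TRUE),
    target = sample(paste0("t", 1:8), 30, TRUE),
    score = sample(600:1000, 30, TRUE), stringsAsFactors = FALSE)
  got <- map_targets_to_theory_groups(syn, theory)
  kept <- syn[syn$score > 700, ]
  for (tg in unique(kept$target)) {
    hs <- unique(kept$herb[kept$target == tg])
    manual <- unlist(lapply(hs, function(h) {
      r <- theory[theory$herb == h, ]
      c(paste0("herb:", h), paste0("qi:", r$qi),
        paste0("flavor:", r$flavors), paste0("meridian:", r$meridians))
    }))
    expect_setequal(got[[tg]], unique(manual))
  }
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  tab <- matrix(c(5, 5, 1, 9), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, 0.1408669, tolerance = 1e-6)
  expect_equal(fisher.test(tab)$p.value, fisher_hypergeom_oracle(tab),
               tolerance = 1e-10)

  flags <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, FALSE), 2, byrow = TRUE,
                  dimnames = list(NULL, paste0("t", 1:4)))
  groups <- list(t1 = "herb:a", t2 = "herb:a", t3 = "herb:b",
                 t4 = "herb:b")
  fe <- fisher_enrichment(flags, groups, "herb:a")
  expect_equal(sum(fe$table), 8)
  expect_equal(fe$p, fisher.test(fe$table)$p.value)
  expect_error(fisher_enrichment(flags, groups, "herb:c"), "empty")
  groups_all <- list(t1 = "herb:a", t2 = "herb:a", t3 = "herb:a",
                     t4 = "herb:a")
  expect_error(fisher_enrichment(flags, groups_all, "herb:a"),
               "complement")
})

test_that("group distance comparisons use Welch's t-test", {
  set.seed(21)
  C <- matrix(c(rnorm(50, 0.5, 0.1), rnorm(50, 0.9, 0.1)), 10, 10)
  colnames(C) <- paste0("t", 1:10)
  groups <- c(lapply(paste0("t", 1:5), function(x) "flavor:a"),
              lapply(paste0("t", 6:10), function(x) "flavor:b"))
  names(groups) <- paste0("t", 1:10)
  res <- compare_group_distances(C, groups, reference = "flavor:a")
  expect_equal(res$p[res$group == "flavor:a"], 1)
  expect_equal(res$t[res$group == "flavor:a"], 0)
  expect_lt(res$p[res$group == "flavor:b"], 1e-10)

  # from-scratch Welch formula agreement
  or <- welch_oracle(as.vector(C[, 6:10]), as.vector(C[, 1:5]))
  expect_equal(res$t[res$group == "flavor:b"], or$t, tolerance = 1e-10)
  expect_equal(res$p[res$group == "flavor:b"], or$p, tolerance = 1e-10)
})

test_that("target contributions summarize finite distances", {
  C <- matrix(c(2, 2, 2, 1, 3, 5, Inf, Inf, Inf), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("t", 1:3)))
  expect_error(target_contribution(C, target = "t3"), "unreachable")
  tc <- target_contribution(C[, 1:2])
  expect_equal(tc$mean[tc$target == "t1"], 2)
  expect_equal(tc$median[tc$target == "t1"], 2)
  expect_equal(tc$mean[tc$target == "t2"], 3)
  expect_equal(tc$target[1], "t1")   # ranked by ascending mean
  expect_error(target_contribution(C, target = "t9"), "unknown")
})

test_that("distance matrices are symmetric and satisfy triangles", {
  cfg <- sim_config(n_genes = 150, n_signature_genes = 10,
                    perturb_effect = 1, noise_sd = 0.3, seed = 13)
  ppi <- generate_ppi_with_perturbation(cfg)
  B <- build_weighted_ppi(ppi$ppi, ppi$perturbation, "inverse")
  genes <- igraph::V(B)$name[1:20]
  C <- distance_matrix(B, genes, genes)
  expect_equal(C, t(C), tolerance = 1e-12)
  set.seed(3)
  for (trial in 1:50) {
    ijk <- sample(20, 3)
    expect_lte(C[ijk[1], ijk[3]],
               C[ijk[1], ijk[2]] + C[ijk[2], ijk[3]] + 1e-12)
  }
})
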