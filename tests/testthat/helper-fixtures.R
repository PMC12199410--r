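# Shared fixtures and independent oracles. Fixtures are generated in code
# (no stored data) and memoized so expensive graphs are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Planted herb-disease fixture: homophilous corpus, strong label coupling.
planted_gat_data <- function(seed, n_herbs = 200, coupling = 4) {
  cfg <- sim_config(n_herbs = n_herbs, n_prescriptions = 2000,
                    label_coupling = coupling, seed = seed)
  herbs <- generate_herb_table(cfg)
  vocab <- build_vocabulary(herbs)
  X <- encode_one_hot(herbs, vocab)
  A <- build_adjacency(count_cooccurrence(generate_prescriptions(cfg, herbs)),
                       herbs$herb_id)
  lab <- generate_disease_labels(cfg, herbs)
  Y <- build_label_matrix(lab$assoc, herbs$herb_id, lab$diseases)
  splits <- sample_node_split(nrow(X), seed + 50)
  list(cfg = cfg, herbs = herbs, vocab = vocab, X = X, A = A,
       lab = lab, Y = Y, splits = splits)
}

planted_gat_config <- function(d, seed) {
  gat_config(in_dim = ncol(d$X), hidden_dim = 32, out_dim = ncol(d$Y),
             heads = 4, dropout = 0.2, learning_rate = 0.01,
             max_epochs = 200, patience = 30, seed = seed)
}

# Planted block fixture for link prediction: 4 blocks of 10 herbs.
block_link_data <- function(seed) {
  cfg <- sim_config(n_herbs = 50, n_prescriptions = 2500,
                    synergy_blocks = split(1:40, rep(1:4, each = 10)),
                    block_boost = 10, seed = seed)
  herbs <- generate_herb_table(cfg)
  X <- encode_one_hot(herbs, build_vocabulary(herbs))
  A <- build_adjacency(count_cooccurrence(generate_prescriptions(cfg, herbs)),
                       herbs$herb_id)
  links <- sample_links(A, seed + 600)
  list(cfg = cfg, herbs = herbs, X = X, A = A, links = links)
}

block_seal_config <- function(seed) {
  seal_config(conv_channels = c(32, 32, 16), max_epochs = 100,
              patience = 15, embedding_dim = 32, seed = seed)
}

# Exhaustive simple-path shortest distance (oracle for Dijkstra): W is a
# symmetric weight matrix with NA for non-edges.
enum_shortest_path <- function(W, from, to) {
  n <- nrow(W)
  best <- Inf
  visit <- function(v, used, acc) {
    if (acc >= best) return(invisible())
    if (v == to) {
      best <<- acc
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!used[u] && !is.na(W[v, u])) {
        used[u] <- TRUE
        visit(u, used, acc + W[v, u])
        used[u] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n)
  used[from] <- TRUE
  if (from == to) return(0)
  visit(from, used, 0)
  best
}

# Two-sided Fisher exact p by direct hypergeometric summation (oracle).
fisher_hypergeom_oracle <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # in-group total
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]   # flagged total
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Welch two-sample t statistic and p from the textbook formulas (oracle).
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Seeded evaluation that restores the caller's RNG state.
with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Tiny deterministic herb table for unit tests.
toy_herbs <- function() {
  data.frame(
    herb_id = c("HA", "HB", "HC"),
    name = c("a", "b", "c"),
    qi = c("warm", "cold", "warm"),
    flavors = c("pungent", "sweet;bitter", "pungent"),
    meridians = c("lung", "liver", "lung;spleen"),
    syndromes = c("", "wind", ""),
    stringsAsFactors = FALSE
  )
}
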