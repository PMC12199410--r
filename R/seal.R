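# Enclosing-subgraph link prediction (SEAL-style): for each candidate herb
# pair an h-hop enclosing subgraph is extracted (the target edge removed to
# prevent label leakage), nodes get Double-Radius structural labels plus
# pretrained global embeddings plus theory features, and a deep graph
# convolutional network (degree-normalized graph convolutions, global sort
# pooling, 1-D convolution, dense readout) classifies the pair.

#' SEAL hyperparameter configuration
#'
#' @param hops Enclosing-subgraph radius (default 1).
#' @param sortpool_k Sort-pooling size; `NULL` picks the 60th percentile of
#'   training subgraph sizes.
#' @param conv_channels Graph-convolution channel sizes (last layer is the
#'   sort channel).
#' @param conv_filters 1-D convolution filter count.
#' @param label_cap Structural labels above this are clamped into one
#'   bucket.
#' @param embedding_dim Pretrained node embedding dimension.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate on the pooled representation (default 0.5).
#' @param max_epochs,patience Training cap and early-stopping patience.
#' @param seed Seed for initialization/dropout.
#' @return A list of class `seal_config`.
#' @export
seal_config <- function(hops = 1, sortpool_k = NULL,
                        conv_channels = c(16, 16, 8), conv_filters = 8,
                        label_cap = 8, embedding_dim = 16,
                        learning_rate = 0.01, dropout = 0.5,
                        max_epochs = 60, patience = 10, seed = 1) {
  stopifnot(hops >= 1, dropout >= 0, dropout < 1)
  structure(list(hops = hops, sortpool_k = sortpool_k,
                 conv_channels = conv_channels, conv_filters = conv_filters,
                 label_cap = label_cap, embedding_dim = embedding_dim,
                 learning_rate = learning_rate, dropout = dropout,
                 max_epochs = max_epochs, patience = patience, seed = seed),
            class = "seal_config")
}

#' Extract the enclosing subgraph of a candidate link
#'
#' Induced subgraph on the union of the `hops`-neighborhoods of the two
#' anchor nodes, with the (i, j) edge itself removed if present (no label
#' leakage). Nodes receive Double-Radius structural labels: both anchors
#' get label 1, any node unreachable from either anchor gets label 0, and
#' every other node gets `1 + min(dx, dy) + (d/2)((d/2) + d %% 2 - 1)`
#' with `d = dx + dy`, so labels encode the distance pair to the anchors.
#'
#' @param A Adjacency matrix.
#' @param i,j Anchor node indices (`i != j`).
#' @param hops Neighborhood radius.
#' @return List with `nodes` (original indices, anchors first), `A_sub`
#'   (subgraph adjacency, target edge removed), `labels` (structural
#'   labels per subgraph node), `anchors` (positions 1:2).
#' @export
extract_enclosing_subgraph <- function(A, i, j, hops = 1) {
  n <- nrow(A)
  if (i == j) stop("anchors must differ")
  if (i < 1 || j < 1 || i > n || j > n) stop("anchor node out of range")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ball <- igraph::ego(g, order = hops, nodes = c(i, j))
  nodes <- sort(unique(c(i, j, unlist(lapply(ball, as.integer)))))
  nodes <- c(i, j, setdiff(nodes, c(i, j)))
  A_sub <- A[nodes, nodes, drop = FALSE]
  A_sub[1, 2] <- 0L
  A_sub[2, 1] <- 0L
  gs <- igraph::graph_from_adjacency_matrix(A_sub, mode = "undirected")
  dx <- as.vector(igraph::distances(gs, v = 1))
  dy <- as.vector(igraph::distances(gs, v = 2))
  d <- dx + dy
  dmin <- pmin(dx, dy)
  lab <- ifelse(is.infinite(d), 0,
                1 + dmin + (d %/% 2) * ((d %/% 2) + d %% 2 - 1))
  lab[1:2] <- 1
  list(nodes = nodes, A_sub = A_sub, labels = as.integer(lab),
       anchors = 1:2)
}

# Node information matrix M_G = (one-hot l_v, e_v, f_v).
node_info_matrix <- function(sub, embeddings, features, label_cap) {
  lab <- pmin(sub$labels, label_cap)
  L <- matrix(0, length(lab), label_cap + 1)
  L[cbind(seq_along(lab), lab + 1)] <- 1
  cbind(L, embeddings[sub$nodes, , drop = FALSE],
        features[sub$nodes, , drop = FALSE])
}

# Symmetric degree normalization 1/sqrt(d_v d_u), neighbors only (no
# self-loop); zero-degree rows stay zero.
gcn_norm_matrix <- function(A_sub) {
  deg <- rowSums(A_sub)
  s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A_sub * outer(s, s)
}

#' Binary cross-entropy loss on logits
#'
#' `L = -1/N sum y log sigma(x) + (1 - y) log(1 - sigma(x))` with the
#' standard logistic `sigma(x) = 1 / (1 + exp(-x))`; logs are clamped for
#' numerical safety.
#'
#' @param logits Numeric vector of raw model outputs.
#' @param y Binary labels.
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(logits, y) {
  stopifnot(length(logits) == length(y), all(y %in% c(0, 1)))
  p <- sigmoid(logits)
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

seal_init_params <- function(in_dim, config, k) {
  ch <- config$conv_channels
  with_seed(config$seed, {
    dims <- c(in_dim, ch)
    Wg <- lapply(seq_along(ch), function(l) glorot(dims[l], dims[l + 1]))
    Ct <- sum(ch)
    list(Wg = Wg, Wc = glorot(Ct, config$conv_filters),
         bc = numeric(config$conv_filters),
         Wd = glorot(k, config$conv_filters) * 0.1, b = 0)
  })
}

# Canonical sort-pooling order: lexicographic descending over channels
# read from the last (sort) channel backwards, so the pooled matrix is
# invariant to any input node permutation.
sortpool_order <- function(Hcat) {
  keys <- lapply(rev(seq_len(ncol(Hcat))), function(c) -Hcat[, c])
  do.call(order, keys)
}

#' DGCNN forward pass on one enclosing subgraph
#'
#' Stacked degree-normalized graph convolutions (LeakyReLU), channel
#' concatenation, global sort pooling to `k` nodes, a per-node 1-D
#' convolution, and a dense readout producing a scalar logit.
#'
#' @param M Node information matrix for the subgraph.
#' @param A_sub Subgraph adjacency.
#' @param params Parameters from [train_seal()] (`$params`).
#' @param k Sort-pooling size.
#' @param keep_cache Return intermediates for backprop.
#' @return The logit (numeric scalar), or a list of intermediates when
#'   `keep_cache = TRUE`.
#' @export
dgcnn_forward <- function(M, A_sub, params, k, keep_cache = FALSE) {
  if (nrow(M) == 0) stop("degenerate input: empty subgraph")
  N <- gcn_norm_matrix(A_sub)
  Hs <- list(); Zs <- list()
  H <- M
  for (l in seq_along(params$Wg)) {
    Z <- N %*% (H %*% params$Wg[[l]])
    H <- leaky_relu(Z)
    Zs[[l]] <- Z; Hs[[l]] <- H
  }
  Hcat <- do.call(cbind, Hs)
  ord <- sortpool_order(Hcat)
  kk <- min(k, nrow(Hcat))
  Hp <- matrix(0, k, ncol(Hcat))
  Hp[seq_len(kk), ] <- Hcat[ord[seq_len(kk)], , drop = FALSE]
  Cv <- Hp %*% params$Wc +
    matrix(params$bc, k, length(params$bc), byrow = TRUE)
  Hc <- leaky_relu(Cv)
  logit <- sum(Hc * params$Wd) + params$b
  if (!keep_cache) return(logit)
  list(logit = logit, N = N, M = M, Zs = Zs, Hs = Hs, Hcat = Hcat,
       ord = ord, kk = kk, Hp = Hp, Cv = Cv, Hc = Hc)
}

# Gradients of the logit path for one subgraph given dlogit.
dgcnn_backward <- function(cache, params, dlogit) {
  grads <- list()
  grads$b <- dlogit
  grads$Wd <- dlogit * cache$Hc
  dHc <- dlogit * params$Wd
  dCv <- dHc * leaky_relu_grad(cache$Cv)
  grads$Wc <- t(cache$Hp) %*% dCv
  grads$bc <- colSums(dCv)
  dHp <- dCv %*% t(params$Wc)
  dHcat <- matrix(0, nrow(cache$Hcat), ncol(cache$Hcat))
  if (cache$kk > 0) {
    dHcat[cache$ord[seq_len(cache$kk)], ] <- dHp[seq_len(cache$kk), ,
                                                 drop = FALSE]
  }
  ch <- vapply(cache$Hs, ncol, integer(1))
  ends <- cumsum(ch)
  starts <- ends - ch + 1
  L <- length(params$Wg)
  dH <- vector("list", L)
  for (l in seq_len(L)) {
    dH[[l]] <- dHcat[, starts[l]:ends[l], drop = FALSE]
  }
  grads$Wg <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- dH[[l]] * leaky_relu_grad(cache$Zs[[l]])
    Hin <- if (l == 1) cache$M else cache$Hs[[l - 1]]
    grads$Wg[[l]] <- t(Hin) %*% (t(cache$N) %*% dZ)
    if (l > 1) {
      dH[[l - 1]] <- dH[[l - 1]] + (t(cache$N) %*% dZ) %*% t(params$Wg[[l]])
    }
  }
  grads
}

seal_flatten <- function(p) {
  out <- list()
  for (l in seq_along(p$Wg)) out[[paste0("Wg", l)]] <- p$Wg[[l]]
  out$Wc <- p$Wc; out$bc <- p$bc; out$Wd <- p$Wd; out$b <- p$b
  out
}

seal_unflatten <- function(flat, template) {
  for (l in seq_along(template$Wg)) template$Wg[[l]] <- flat[[paste0("Wg", l)]]
  template$Wc <- flat$Wc; template$bc <- flat$bc
  template$Wd <- flat$Wd; template$b <- flat$b
  template
}

seal_prepare <- function(links, A, features, config, embeddings) {
  lapply(seq_len(nrow(links)), function(r) {
    sub <- extract_enclosing_subgraph(A, links$i[r], links$j[r],
                                      hops = config$hops)
    list(M = node_info_matrix(sub, embeddings, features, config$label_cap),
         A_sub = sub$A_sub, label = links$label[r], split = links$split[r])
  })
}

seal_loss_grads <- function(items, flatp, template, k) {
  params <- seal_unflatten(flatp, template)
  n <- length(items)
  total <- NULL
  loss <- 0
  for (it in items) {
    cache <- dgcnn_forward(it$M, it$A_sub, params, k, keep_cache = TRUE)
    p <- sigmoid(cache$logit)
    eps <- 1e-12
    loss <- loss - (it$label * log(max(p, eps)) +
                      (1 - it$label) * log(max(1 - p, eps)))
    g <- dgcnn_backward(cache, params, (p - it$label) / n)
    fg <- seal_flatten(g)
    if (is.null(total)) total <- fg else {
      for (nm in names(fg)) total[[nm]] <- total[[nm]] + fg[[nm]]
    }
  }
  list(loss = loss / n, grads = total)
}

seal_eval_logits <- function(items, params, k) {
  vapply(items, function(it) dgcnn_forward(it$M, it$A_sub, params, k),
         numeric(1))
}

#' Train the SEAL herb-herb combination model
#'
#' Extracts enclosing subgraphs for every link in the dataset, pretrains
#' global node embeddings, and optimizes the DGCNN with Adam and early
#' stopping on validation loss. AP and ROC-AUC are reported on the test
#' split.
#'
#' @param links Link dataset from [sample_links()].
#' @param A Adjacency matrix of the global herb graph.
#' @param features Herb feature matrix (rows aligned with `A`).
#' @param config A [seal_config()].
#' @return List of class `seal_model` with `params`, `config`, `k`,
#'   `embeddings`, `ap`, `auc`, `history`.
#' @export
train_seal <- function(links, A, features, config) {
  stopifnot(all(c("i", "j", "label", "split") %in% names(links)))
  embeddings <- pretrain_embeddings(A, config$embedding_dim, config$seed)
  items <- seal_prepare(links, A, features, config, embeddings)
  sizes <- vapply(items, function(it) nrow(it$M), numeric(1))
  k <- config$sortpool_k %||%
    max(4L, as.integer(ceiling(quantile(sizes, 0.6))))
  tr <- items[links$split == "train"]
  va <- items[links$split == "val"]
  te <- items[links$split == "test"]
  if (!length(tr) || !length(va) || !length(te)) {
    stop("invalid split: each of train/val/test must be nonempty")
  }
  in_dim <- ncol(items[[1]]$M)
  params <- seal_init_params(in_dim, config, k)
  flat <- seal_flatten(params)
  opt <- adam_new()
  best <- list(val = Inf, flat = flat, epoch = 0)
  wait <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  y_va <- vapply(va, `[[`, numeric(1), "label")
  for (epoch in seq_len(config$max_epochs)) {
    lg <- seal_loss_grads(tr, flat, params, k)
    st <- adam_step(opt, lg$grads, flat, config$learning_rate)
    opt <- st$state; flat <- st$params
    cur <- seal_unflatten(flat, params)
    val_loss <- bce_loss(seal_eval_logits(va, cur, k), y_va)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = lg$loss,
                                         val_loss = val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, flat = flat, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  params <- seal_unflatten(best$flat, params)
  te_logits <- seal_eval_logits(te, params, k)
  y_te <- vapply(te, `[[`, numeric(1), "label")
  structure(list(params = params, config = config, k = k,
                 embeddings = embeddings,
                 ap = average_precision(te_logits, y_te),
                 auc = roc_auc(te_logits, y_te),
                 history = history, best_epoch = best$epoch),
            class = "seal_model")
}

#' Score and rank candidate partner herbs for one herb
#'
#' @param model A `seal_model` from [train_seal()].
#' @param A Adjacency matrix used in training.
#' @param features Herb feature matrix.
#' @param herb Herb index (row of `A`) or herb ID matching
#'   `rownames(A)`.
#' @param candidates Candidate partner indices (default: all other herbs).
#' @param top_k Number of partners to return.
#' @param novel_only Drop candidates already linked to `herb` in `A`.
#' @return Data.frame `partner`, `score` (link probability), descending,
#'   ties broken by partner ID.
#' @export
recommend_pairs <- function(model, A, features, herb, candidates = NULL,
                            top_k = 10, novel_only = TRUE) {
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  h <- if (is.character(herb)) match(herb, ids) else herb
  if (is.na(h) || h < 1 || h > nrow(A)) stop("unknown herb: ", herb)
  cand <- candidates %||% setdiff(seq_len(nrow(A)), h)
  if (novel_only) cand <- cand[A[h, cand] == 0]
  if (!length(cand)) {
    return(data.frame(partner = character(), score = numeric()))
  }
  scores <- vapply(cand, function(cd) {
    sub <- extract_enclosing_subgraph(A, h, cd, hops = model$config$hops)
    M <- node_info_matrix(sub, model$embeddings, features,
                          model$config$label_cap)
    sigmoid(dgcnn_forward(M, sub$A_sub, model$params, model$k))
  }, numeric(1))
  df <- data.frame(partner = ids[cand], score = scores,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$partner), ]
  rownames(df) <- NULL
  head(df, n = min(top_k, nrow(df)))
}

#' Link-prediction baselines (GCN, random-walk embeddings)
#'
#' `graph-convolution`: a two-layer mean-aggregation GCN produces node
#' representations trained so that the inner product of a pair's
#' representations classifies the link. `random-walk-embedding`:
#' pretrained structural embeddings scored by logistic regression on the
#' element-wise product of the pair's embeddings.
#'
#' @param links Link dataset from [sample_links()].
#' @param A Adjacency matrix (training edges only are visible to the
#'   models through `A`).
#' @param features Herb feature matrix (used by the GCN).
#' @param kind `"graph-convolution"` or `"random-walk-embedding"`.
#' @param seed Seed.
#' @return List with `ap`, `auc` on the test split and `scores` for all
#'   links.
#' @export
run_link_baseline <- function(links, A, features,
                              kind = c("graph-convolution",
                                       "random-walk-embedding"),
                              seed = 1) {
  kind <- match.arg(kind)
  tr <- links$split == "train"
  te <- links$split == "test"
  if (kind == "random-walk-embedding") {
    E <- pretrain_embeddings(A, min(16, nrow(A)), seed)
    had <- E[links$i, , drop = FALSE] * E[links$j, , drop = FALSE]
    df <- as.data.frame(had)
    names(df) <- paste0("e", seq_len(ncol(had)))
    dtr <- cbind(df[tr, , drop = FALSE], .y = links$label[tr])
    fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
    scores <- suppressWarnings(predict(fit, newdata = df,
                                       type = "response"))
  } else {
    scores <- gcn_link_scores(links, A, features, seed)
  }
  list(ap = average_precision(scores[te], links$label[te]),
       auc = roc_auc(scores[te], links$label[te]),
       scores = scores, kind = kind)
}

# Two-layer GCN with inner-product link decoder, BCE on training links.
gcn_link_scores <- function(links, A, features, seed, hidden = 32,
                            out_dim = 16, lr = 0.05, epochs = 100,
                            patience = 10) {
  N <- mean_agg_matrix(A)
  NX <- N %*% features
  params <- with_seed(seed, list(W1 = glorot(ncol(features), hidden),
                                 W2 = glorot(hidden, out_dim)))
  opt <- adam_new()
  tr <- which(links$split == "train")
  va <- which(links$split == "val")
  y <- links$label
  link_loss <- function(Z, idx) {
    s <- rowSums(Z[links$i[idx], , drop = FALSE] *
                   Z[links$j[idx], , drop = FALSE])
    bce_loss(s, y[idx])
  }
  best <- list(val = Inf, params = params)
  wait <- 0
  for (epoch in seq_len(epochs)) {
    Z1 <- NX %*% params$W1
    H1 <- leaky_relu(Z1)
    NH1 <- N %*% H1
    Z <- NH1 %*% params$W2
    s <- rowSums(Z[links$i[tr], , drop = FALSE] *
                   Z[links$j[tr], , drop = FALSE])
    p <- sigmoid(s)
    dres <- (p - y[tr]) / length(tr)
    dZ <- matrix(0, nrow(Z), ncol(Z))
    for (r in seq_along(tr)) {
      ii <- links$i[tr[r]]; jj <- links$j[tr[r]]
      dZ[ii, ] <- dZ[ii, ] + dres[r] * Z[jj, ]
      dZ[jj, ] <- dZ[jj, ] + dres[r] * Z[ii, ]
    }
    dW2 <- t(NH1) %*% dZ
    dH1 <- t(N) %*% (dZ %*% t(params$W2))
    dZ1 <- dH1 * leaky_relu_grad(Z1)
    dW1 <- t(NX) %*% dZ1
    st <- adam_step(opt, list(W1 = dW1, W2 = dW2), params, lr)
    opt <- st$state; params <- st$params
    Zv <- N %*% leaky_relu(NX %*% params$W1) %*% params$W2
    val <- link_loss(Zv, va)
    if (val < best$val - 1e-9) {
      best <- list(val = val, params = params); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  params <- best$params
  Z <- N %*% leaky_relu(NX %*% params$W1) %*% params$W2
  sigmoid(rowSums(Z[links$i, , drop = FALSE] * Z[links$j, , drop = FALSE]))
}
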