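# Two-layer multi-head graph attention network for multi-label node
# classification, written in base R with analytic backpropagation (verified
# against finite differences in the test suite). Multi-head outputs are
# concatenated after layer 1 and averaged at layer 2; hidden activations
# are LeakyReLU and the output layer emits logits for a
# binary-cross-entropy-with-logits loss.

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' GAT hyperparameter configuration
#'
#' @param in_dim Input feature dimension f.
#' @param hidden_dim Total hidden width after head concatenation (default
#'   256; must be divisible by `heads`).
#' @param out_dim Number of disease labels c (default 14).
#' @param heads Attention heads (default 8).
#' @param dropout Feature dropout rate applied before each layer.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Training epoch cap (default 100).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param seed Seed for initialization and dropout.
#' @return A list of class `gat_config`.
#' @export
gat_config <- function(in_dim, hidden_dim = 256, out_dim = 14, heads = 8,
                       dropout = 0.2, learning_rate = 0.01,
                       max_epochs = 100, patience = 10, seed = 1) {
  stopifnot(in_dim >= 1, hidden_dim >= 1, out_dim >= 1, heads >= 1,
            dropout >= 0, dropout < 1)
  if (hidden_dim %% heads != 0) {
    stop("hidden_dim must be divisible by heads")
  }
  structure(list(in_dim = in_dim, hidden_dim = hidden_dim,
                 out_dim = out_dim, heads = heads, dropout = dropout,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, seed = seed),
            class = "gat_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Parameter container: layer 1 has `heads` heads of width hidden/heads
# (concatenated); layer 2 has `heads` heads of width out_dim (averaged).
gat_init_params <- function(config) {
  with_seed(config$seed, {
    d1 <- config$hidden_dim %/% config$heads
    l1 <- lapply(seq_len(config$heads), function(k) {
      list(W = glorot(config$in_dim, d1),
           a_src = runif(d1, -0.1, 0.1), a_dst = runif(d1, -0.1, 0.1))
    })
    l2 <- lapply(seq_len(config$heads), function(k) {
      list(W = glorot(config$hidden_dim, config$out_dim),
           a_src = runif(config$out_dim, -0.1, 0.1),
           a_dst = runif(config$out_dim, -0.1, 0.1))
    })
    list(layer1 = l1, layer2 = l2)
  })
}

# Directed edge list (i <- j aggregation pairs) with self-loops, from a
# symmetric adjacency matrix.
gat_edges <- function(A) {
  n <- nrow(A)
  idx <- which(A != 0, arr.ind = TRUE)
  ei <- c(idx[, 1], seq_len(n))
  ej <- c(idx[, 2], seq_len(n))
  o <- order(ei, ej)
  list(i = ei[o], j = ej[o], n = n)
}

#' Attention coefficients for one GAT head
#'
#' Computes `alpha_ij = softmax_j LeakyReLU(a^T [W h_i || W h_j])` over
#' each node's neighborhood (self-loops included). Returned per edge.
#'
#' @param H Node feature matrix (n x p).
#' @param edges Edge structure from adjacency (internal; self-loops
#'   included), a list with integer vectors `i`, `j`.
#' @param W Weight matrix (p x d).
#' @param a Attention vector of length 2d (first half applied to the
#'   source/center node transform, second half to the neighbor transform).
#' @return List with `alpha` (per edge), `edges`, and the transformed
#'   features `S = H W`.
#' @export
attention_coefficients <- function(H, edges, W, a) {
  d <- ncol(W)
  if (length(a) != 2 * d) {
    stop(sprintf("attention vector length %d does not match 2 x %d",
                 length(a), d))
  }
  fw <- gat_head_forward(H, edges, W, a[seq_len(d)], a[d + seq_len(d)])
  list(alpha = fw$alpha, edges = edges, S = fw$S)
}

# Forward pass of a single attention head. Returns intermediates needed
# for backprop.
gat_head_forward <- function(H, edges, W, a_src, a_dst, slope = 0.2) {
  S <- H %*% W
  f <- as.vector(S %*% a_src)
  g <- as.vector(S %*% a_dst)
  e_pre <- f[edges$i] + g[edges$j]
  e <- leaky_relu(e_pre, slope)
  m <- stats::ave(e, edges$i, FUN = max)
  ex <- exp(e - m)
  denom <- rowsum(ex, edges$i)[, 1]
  alpha <- ex / denom[edges$i]
  Z <- rowsum(alpha * S[edges$j, , drop = FALSE], edges$i)
  list(S = S, e_pre = e_pre, alpha = alpha, Z = Z)
}

# Backward pass of a single attention head. dZ is the gradient at the
# aggregated output. Returns gradients for W, a_src, a_dst and the input H.
gat_head_backward <- function(H, edges, W, a_src, a_dst, fw, dZ,
                              slope = 0.2) {
  S <- fw$S; alpha <- fw$alpha
  dalpha <- rowSums(dZ[edges$i, , drop = FALSE] *
                      S[edges$j, , drop = FALSE])
  dS <- rowsum(alpha * dZ[edges$i, , drop = FALSE], edges$j)
  ci <- rowsum(alpha * dalpha, edges$i)[, 1]
  dE <- alpha * (dalpha - ci[edges$i])
  de_pre <- dE * leaky_relu_grad(fw$e_pre, slope)
  df <- rowsum(de_pre, edges$i)[, 1]
  dg <- rowsum(de_pre, edges$j)[, 1]
  # rowsum orders groups by sorted unique value; self-loops guarantee all
  # nodes appear in both i and j, so rows align with 1..n.
  dS <- dS + outer(df, a_src) + outer(dg, a_dst)
  da_src <- as.vector(t(S) %*% df)
  da_dst <- as.vector(t(S) %*% dg)
  dW <- t(H) %*% dS
  dH <- dS %*% t(W)
  list(dW = dW, da_src = da_src, da_dst = da_dst, dH = dH)
}

# Full forward pass. dropout_masks NULL at evaluation time.
gat_forward_full <- function(X, edges, params, config, dropout_masks = NULL) {
  H0 <- if (!is.null(dropout_masks)) X * dropout_masks$m0 else X
  fw1 <- lapply(params$layer1, function(p)
    gat_head_forward(H0, edges, p$W, p$a_src, p$a_dst))
  Z1 <- do.call(cbind, lapply(fw1, `[[`, "Z"))
  H1 <- leaky_relu(Z1)
  H1d <- if (!is.null(dropout_masks)) H1 * dropout_masks$m1 else H1
  fw2 <- lapply(params$layer2, function(p)
    gat_head_forward(H1d, edges, p$W, p$a_src, p$a_dst))
  logits <- Reduce(`+`, lapply(fw2, `[[`, "Z")) / length(fw2)
  list(H0 = H0, fw1 = fw1, Z1 = Z1, H1 = H1, H1d = H1d, fw2 = fw2,
       logits = logits)
}

#' GAT forward pass: per-herb, per-disease scores
#'
#' @param X Feature matrix (n x f).
#' @param A Symmetric adjacency matrix (self-loops are added internally).
#' @param params Parameters from training (or [gat_init_params] internally).
#' @param config A [gat_config()].
#' @return Matrix (n x c) of association probabilities.
#' @export
gat_forward <- function(X, A, params, config) {
  stopifnot(nrow(X) == nrow(A), ncol(X) == config$in_dim)
  edges <- gat_edges(A)
  fw <- gat_forward_full(X, edges, params, config)
  sc <- sigmoid(fw$logits)
  dimnames(sc) <- list(rownames(X), NULL)
  sc
}

# Mean BCE-with-logits over masked rows; returns loss and gradient.
bce_masked <- function(logits, Y, mask) {
  p <- sigmoid(logits)
  eps <- 1e-12
  lmat <- -(Y * log(pmax(p, eps)) + (1 - Y) * log(pmax(1 - p, eps)))
  loss <- mean(lmat[mask, , drop = FALSE])
  dl <- matrix(0, nrow(logits), ncol(logits))
  nm <- sum(mask) * ncol(Y)
  dl[mask, ] <- (p[mask, , drop = FALSE] - Y[mask, , drop = FALSE]) / nm
  list(loss = loss, grad = dl)
}

adam_new <- function() list(t = 0)

# `grads` and `params` are matched by name (gradient lists may be built in
# a different order than the parameter list).
adam_step <- function(state, grads, params, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  stopifnot(!is.null(names(grads)), all(names(grads) %in% names(params)))
  state$t <- state$t + 1
  if (is.null(state$m)) {
    state$m <- lapply(grads, function(g) g * 0)
    state$v <- lapply(grads, function(g) g * 0)
  }
  for (k in names(grads)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# Flatten / unflatten GAT params for the optimizer.
gat_flatten <- function(params) {
  out <- list()
  for (l in c("layer1", "layer2")) {
    for (k in seq_along(params[[l]])) {
      for (nm in c("W", "a_src", "a_dst")) {
        out[[paste(l, k, nm, sep = ".")]] <- params[[l]][[k]][[nm]]
      }
    }
  }
  out
}

gat_unflatten <- function(flat, template) {
  for (l in c("layer1", "layer2")) {
    for (k in seq_along(template[[l]])) {
      for (nm in c("W", "a_src", "a_dst")) {
        template[[l]][[k]][[nm]] <- flat[[paste(l, k, nm, sep = ".")]]
      }
    }
  }
  template
}

# Analytic gradient of the masked BCE loss w.r.t. every GAT parameter.
gat_gradients <- function(X, edges, params, config, Y, mask,
                          dropout_masks = NULL) {
  fw <- gat_forward_full(X, edges, params, config, dropout_masks)
  lb <- bce_masked(fw$logits, Y, mask)
  K2 <- length(params$layer2)
  dZ2 <- lb$grad / K2
  grads <- list()
  dH1d <- matrix(0, nrow(X), config$hidden_dim)
  for (k in seq_len(K2)) {
    p <- params$layer2[[k]]
    bk <- gat_head_backward(fw$H1d, edges, p$W, p$a_src, p$a_dst,
                            fw$fw2[[k]], dZ2)
    grads[[paste("layer2", k, "W", sep = ".")]] <- bk$dW
    grads[[paste("layer2", k, "a_src", sep = ".")]] <- bk$da_src
    grads[[paste("layer2", k, "a_dst", sep = ".")]] <- bk$da_dst
    dH1d <- dH1d + bk$dH
  }
  dH1 <- if (!is.null(dropout_masks)) dH1d * dropout_masks$m1 else dH1d
  dZ1 <- dH1 * leaky_relu_grad(fw$Z1)
  d1 <- config$hidden_dim %/% length(params$layer1)
  for (k in seq_along(params$layer1)) {
    p <- params$layer1[[k]]
    cols <- (k - 1) * d1 + seq_len(d1)
    bk <- gat_head_backward(fw$H0, edges, p$W, p$a_src, p$a_dst,
                            fw$fw1[[k]], dZ1[, cols, drop = FALSE])
    grads[[paste("layer1", k, "W", sep = ".")]] <- bk$dW
    grads[[paste("layer1", k, "a_src", sep = ".")]] <- bk$da_src
    grads[[paste("layer1", k, "a_dst", sep = ".")]] <- bk$da_dst
  }
  list(loss = lb$loss, grads = grads)
}

#' Train the GAT herb-disease model
#'
#' Adam optimization of the masked binary cross-entropy, early stopping on
#' validation loss with the configured patience, metrics reported on the
#' test split using the best validation parameters. Deterministic under
#' the config seed.
#'
#' @param X Feature matrix.
#' @param A Adjacency matrix.
#' @param Y Label matrix.
#' @param splits Node split masks from [sample_node_split()].
#' @param config A [gat_config()].
#' @return A list of class `gat_model` with `params`, `config`, `metrics`
#'   (a `metrics_report` on the test split), `history` (per-epoch losses),
#'   and `scores` (full n x c probability matrix from the best epoch).
#' @export
train_gat <- function(X, A, Y, splits, config) {
  stopifnot(nrow(X) == nrow(A), nrow(X) == nrow(Y))
  if (!any(splits$train) || !any(splits$val) || !any(splits$test)) {
    stop("invalid split: each of train/val/test must be nonempty")
  }
  edges <- gat_edges(A)
  params <- gat_init_params(config)
  flat <- gat_flatten(params)
  opt <- adam_new()
  best <- list(val = Inf, flat = flat, epoch = 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      dm <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        dm <- list(
          m0 = matrix(rbinom(length(X), 1, keep) / keep, nrow(X)),
          m1 = matrix(rbinom(nrow(X) * config$hidden_dim, 1, keep) / keep,
                      nrow(X))
        )
      }
      params <- gat_unflatten(flat, params)
      gr <- gat_gradients(X, edges, params, config, Y, splits$train, dm)
      st <- adam_step(opt, gr$grads, flat, config$learning_rate)
      opt <- st$state; flat <- st$params
      params <- gat_unflatten(flat, params)
      fw_eval <- gat_forward_full(X, edges, params, config)
      val_loss <- bce_masked(fw_eval$logits, Y, splits$val)$loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = gr$loss,
                                           val_loss = val_loss))
      if (val_loss < best$val - 1e-9) {
        best <- list(val = val_loss, flat = flat, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$patience) break
      }
    }
  })
  params <- gat_unflatten(best$flat, params)
  scores <- gat_forward(X, A, params, config)
  test_metrics <- evaluate_multilabel(scores[splits$test, , drop = FALSE],
                                      Y[splits$test, , drop = FALSE])
  structure(list(params = params, config = config, metrics = test_metrics,
                 history = history, scores = scores,
                 best_epoch = best$epoch),
            class = "gat_model")
}

#' Rank herbs by predicted association with one disease
#'
#' @param scores Score matrix (rownames = herb IDs).
#' @param disease Disease column name or index.
#' @param categories Ordered disease categories (when `disease` is a name).
#' @param known_mask Optional logical/binary vector: herbs already
#'   associated with the disease, excluded when `novel_only = TRUE`.
#' @param top_k Number of herbs to return (default all).
#' @param novel_only Exclude already-associated herbs.
#' @return Data.frame `herb_id`, `score`, sorted by descending score, ties
#'   broken by herb_id.
#' @export
rank_herbs <- function(scores, disease, categories = NULL,
                       known_mask = NULL, top_k = Inf, novel_only = TRUE) {
  j <- if (is.character(disease)) {
    if (is.null(categories) || !disease %in% categories) {
      stop("unknown disease category: ", disease)
    }
    match(disease, categories)
  } else {
    if (disease < 1 || disease > ncol(scores)) {
      stop("unknown disease category index: ", disease)
    }
    disease
  }
  ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  keep <- rep(TRUE, nrow(scores))
  if (novel_only && !is.null(known_mask)) keep <- !(known_mask > 0)
  df <- data.frame(herb_id = ids[keep], score = scores[keep, j],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$herb_id), ]
  rownames(df) <- NULL
  head(df, n = min(top_k, nrow(df)))
}
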