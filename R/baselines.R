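# Baseline models the GAT and SEAL classifiers are compared against:
# one-vs-rest logistic regression, k-nearest-neighbour label averaging, a
# two-layer mean-aggregation graph convolution for node classification,
# and GCN / random-walk-embedding scorers for link prediction.

#' Baseline multi-label node classifiers
#'
#' Fits one of three baselines on the same node splits used by the GAT and
#' reports the same multi-label metrics on the test split.
#'
#' @param X Feature matrix.
#' @param Y Label matrix.
#' @param splits Node split masks from [sample_node_split()].
#' @param kind `"logistic-regression"`, `"k-nearest-neighbor"` or
#'   `"graph-convolution"`.
#' @param A Adjacency matrix (required for `"graph-convolution"`).
#' @param k Neighbour count for KNN (default 5).
#' @param seed Seed (used by the GCN baseline).
#' @return List with `scores` (n x c matrix) and `metrics` (test-split
#'   `metrics_report`).
#' @export
run_baseline <- function(X, Y, splits,
                         kind = c("logistic-regression",
                                  "k-nearest-neighbor",
                                  "graph-convolution"),
                         A = NULL, k = 5, seed = 1) {
  kind <- match.arg(kind)
  scores <- switch(kind,
    "logistic-regression" = lr_scores(X, Y, splits$train),
    "k-nearest-neighbor" = knn_scores(X, Y, splits$train, k),
    "graph-convolution" = {
      if (is.null(A)) stop("graph-convolution baseline requires A")
      gcn_node_scores(X, A, Y, splits, seed)
    })
  metrics <- evaluate_multilabel(scores[splits$test, , drop = FALSE],
                                 Y[splits$test, , drop = FALSE])
  list(scores = scores, metrics = metrics, kind = kind)
}

lr_scores <- function(X, Y, train_mask) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  out <- matrix(0, nrow(X), ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[train_mask, j]
    if (length(unique(y)) < 2) {
      out[, j] <- mean(y)
      next
    }
    dtr <- cbind(df[train_mask, , drop = FALSE], .y = y)
    fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
    out[, j] <- suppressWarnings(predict(fit, newdata = df,
                                         type = "response"))
  }
  dimnames(out) <- dimnames(Y)
  out
}

knn_scores <- function(X, Y, train_mask, k = 5) {
  tr <- which(train_mask)
  D <- as.matrix(stats::dist(X))
  out <- matrix(0, nrow(X), ncol(Y))
  for (i in seq_len(nrow(X))) {
    nb <- tr[order(D[i, tr], tr)][seq_len(min(k, length(tr)))]
    out[i, ] <- colMeans(Y[nb, , drop = FALSE])
  }
  dimnames(out) <- dimnames(Y)
  out
}

# Row-normalized adjacency with self-loops (mean aggregation).
mean_agg_matrix <- function(A) {
  Ah <- A + diag(nrow(A))
  Ah / rowSums(Ah)
}

# Two-layer mean-aggregation GCN trained with Adam + BCE on the train mask.
gcn_node_scores <- function(X, A, Y, splits, seed, hidden = 32,
                            lr = 0.05, epochs = 100, patience = 10) {
  N <- mean_agg_matrix(A)
  params <- with_seed(seed, list(W1 = glorot(ncol(X), hidden),
                                 W2 = glorot(hidden, ncol(Y))))
  opt <- adam_new()
  best <- list(val = Inf, params = params)
  wait <- 0
  NX <- N %*% X
  for (epoch in seq_len(epochs)) {
    Z1 <- NX %*% params$W1
    H1 <- leaky_relu(Z1)
    NH1 <- N %*% H1
    logits <- NH1 %*% params$W2
    lb <- bce_masked(logits, Y, splits$train)
    dW2 <- t(NH1) %*% lb$grad
    dH1 <- t(N) %*% (lb$grad %*% t(params$W2))
    dZ1 <- dH1 * leaky_relu_grad(Z1)
    dW1 <- t(NX) %*% dZ1
    st <- adam_step(opt, list(W1 = dW1, W2 = dW2), params, lr)
    opt <- st$state; params <- st$params
    val <- bce_masked(N %*% leaky_relu(NX %*% params$W1) %*% params$W2,
                      Y, splits$val)$loss
    if (val < best$val - 1e-9) {
      best <- list(val = val, params = params); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  params <- best$params
  out <- sigmoid(N %*% leaky_relu(NX %*% params$W1) %*% params$W2)
  dimnames(out) <- dimnames(Y)
  out
}

#' Random-walk structural node embeddings
#'
#' Deterministic random-walk embeddings of the global herb graph: the
#' window-averaged random-walk co-visiting matrix (transition matrix powers
#' up to `window`) is shifted-log transformed and factorized by truncated
#' SVD, the classical closed-form counterpart of skip-gram random-walk
#' embedding training.
#'
#' @param A Adjacency matrix.
#' @param dim Embedding dimension.
#' @param seed Seed (kept for interface stability; the factorization is
#'   deterministic).
#' @param window Random-walk window (default 5).
#' @return Matrix n x dim of embeddings.
#' @export
pretrain_embeddings <- function(A, dim, seed = 1, window = 5) {
  n <- nrow(A)
  if (n == 0) stop("empty adjacency")
  deg <- rowSums(A)
  P <- A / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0
  M <- matrix(0, n, n)
  Pk <- diag(n)
  for (w in seq_len(window)) {
    Pk <- Pk %*% P
    M <- M + Pk
  }
  M <- log1p(M / window * n)
  sv <- svd(M, nu = min(dim, n), nv = 0)
  d_use <- min(dim, n)
  E <- sv$u %*% diag(sqrt(sv$d[seq_len(d_use)]), d_use)
  if (d_use < dim) E <- cbind(E, matrix(0, n, dim - d_use))
  rownames(E) <- rownames(A)
  E
}
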