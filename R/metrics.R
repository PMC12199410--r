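# Multi-label ranking metrics (average precision, ROC-AUC, label ranking
# average precision, label ranking loss), following the standard
# threshold-based definitions so that results are comparable with the
# common Python implementations.

#' Micro-averaged average precision
#'
#' Scores and labels are flattened; AP = sum over distinct score
#' thresholds of (R_k - R_{k-1}) * P_k with precision/recall computed at
#' each threshold.
#'
#' @param scores Numeric vector or matrix.
#' @param y Binary vector or matrix, same shape.
#' @return AP in [0, 1].
#' @export
average_precision <- function(scores, y) {
  s <- as.vector(scores)
  yy <- as.vector(y)
  n_pos <- sum(yy == 1)
  if (n_pos == 0) stop("average precision undefined: no positive labels")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; yy <- yy[o]
  grp_end <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(yy == 1)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Binary ROC-AUC by the rank (Mann-Whitney) formula with tie correction
#'
#' @param scores Numeric vector.
#' @param y Binary vector.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("ROC-AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Macro ROC-AUC over label columns; single-class columns are skipped and
# recorded.
macro_roc_auc <- function(scores, Y) {
  ok <- which(colSums(Y == 1) > 0 & colSums(Y == 0) > 0)
  if (!length(ok)) {
    stop("ROC-AUC undefined for every label column (single-class labels)")
  }
  aucs <- vapply(ok, function(j) roc_auc(scores[, j], Y[, j]), numeric(1))
  structure(mean(aucs), skipped = setdiff(seq_len(ncol(Y)), ok))
}

#' Label ranking average precision (sample-wise)
#'
#' For each sample, each true label's precision-at-its-rank is averaged
#' (ties counted with >=); samples with all-zero or all-one label rows
#' contribute 1.
#'
#' @param scores Score matrix (samples x labels).
#' @param Y Binary label matrix.
#' @return LRAP in (0, 1].
#' @export
lrap <- function(scores, Y) {
  vals <- vapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]; s <- scores[i, ]
    rel <- which(y == 1)
    if (length(rel) == 0 || length(rel) == length(y)) return(1)
    mean(vapply(rel, function(j) {
      ge <- s >= s[j]
      sum(ge & y == 1) / sum(ge)
    }, numeric(1)))
  }, numeric(1))
  mean(vals)
}

#' Label ranking loss (sample-wise)
#'
#' Average fraction of (true, false) label pairs that are incorrectly
#' ordered; a tie between a true and a false label counts as an error (the
#' false label is not ranked strictly below the true one). Degenerate rows
#' (no true or no false labels) contribute 0.
#'
#' @param scores Score matrix.
#' @param Y Binary label matrix.
#' @return LRL in [0, 1].
#' @export
label_ranking_loss <- function(scores, Y) {
  vals <- vapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]; s <- scores[i, ]
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) return(0)
    st <- s[y == 1]; sf <- s[y == 0]
    bad <- sum(vapply(st, function(v) sum(sf >= v), numeric(1)))
    bad / (n1 * n0)
  }, numeric(1))
  mean(vals)
}

#' Full multi-label metrics report
#'
#' Computes micro-averaged AP, macro-averaged ROC-AUC, LRAP and label
#' ranking loss for a score/label matrix pair.
#'
#' @param scores Score matrix (herbs x diseases).
#' @param Y Binary label matrix, same shape.
#' @return A list of class `metrics_report` with fields `ap`, `roc_auc`,
#'   `lrap`, `lrl`, `skipped_columns` and `averaging`.
#' @export
evaluate_multilabel <- function(scores, Y) {
  stopifnot(all(dim(scores) == dim(Y)))
  if (all(Y == 1) || all(Y == 0)) {
    stop("metrics undefined: label matrix is single-class everywhere")
  }
  auc <- macro_roc_auc(scores, Y)
  structure(list(
    ap = average_precision(scores, Y),
    roc_auc = as.numeric(auc),
    lrap = lrap(scores, Y),
    lrl = label_ranking_loss(scores, Y),
    skipped_columns = attr(auc, "skipped"),
    averaging = c(ap = "micro", roc_auc = "macro", lrap = "sample",
                  lrl = "sample")
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AP = %.4f  ROC-AUC = %.4f  LRAP = %.4f  LRL = %.4f\n",
              x$ap, x$roc_auc, x$lrap, x$lrl))
  if (length(x$skipped_columns)) {
    cat("ROC-AUC skipped single-class columns:",
        paste(x$skipped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}
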