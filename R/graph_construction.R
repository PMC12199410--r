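#' Count herb pair co-occurrence across prescriptions
#'
#' @param corpus A `prescription_corpus` (list of herb-ID vectors).
#' @return A data.frame with columns `herb_a`, `herb_b` (with
#'   `herb_a < herb_b`) and `count`, one row per pair observed at least
#'   once.
#' @export
count_cooccurrence <- function(corpus) {
  empty <- data.frame(herb_a = character(), herb_b = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!length(corpus)) return(empty)
  keys <- unlist(lapply(corpus, function(p) {
    p <- sort(unique(p))
    if (length(p) < 2) return(character())
    cmb <- utils::combn(p, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\t")
  }))
  if (!length(keys)) return(empty)
  tab <- table(keys)
  parts <- do.call(rbind, strsplit(names(tab), "\t", fixed = TRUE))
  out <- data.frame(herb_a = parts[, 1], herb_b = parts[, 2],
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$herb_a, out$herb_b), ]
  rownames(out) <- NULL
  out
}

#' Binarize co-occurrence counts into a herb-herb adjacency matrix
#'
#' An edge is kept when the pair appeared in strictly more than `min_count`
#' prescriptions (with `strict = TRUE`, the default, a count of exactly
#' `min_count` yields no edge). The matrix is symmetric with a zero
#' diagonal.
#'
#' @param counts Pair-count table from [count_cooccurrence()].
#' @param herb_ids Full ordered herb index (character).
#' @param min_count Co-occurrence threshold (default 5).
#' @param strict If `TRUE`, require `count > min_count`; else `>=`.
#' @return Binary integer matrix, dims `length(herb_ids)` squared.
#' @export
build_adjacency <- function(counts, herb_ids, min_count = 5, strict = TRUE) {
  A <- matrix(0L, length(herb_ids), length(herb_ids),
              dimnames = list(herb_ids, herb_ids))
  keep <- if (strict) counts$count > min_count else counts$count >= min_count
  kc <- counts[keep & counts$herb_a %in% herb_ids &
                 counts$herb_b %in% herb_ids, ]
  if (nrow(kc)) {
    ia <- match(kc$herb_a, herb_ids)
    ib <- match(kc$herb_b, herb_ids)
    A[cbind(ia, ib)] <- 1L
    A[cbind(ib, ia)] <- 1L
  }
  diag(A) <- 0L
  A
}

#' Build the herb x disease label matrix
#'
#' @param assoc Association data.frame (`herb_id`, `disease`).
#' @param herb_ids Ordered herb index.
#' @param categories Ordered disease category vector.
#' @return Binary integer matrix herbs x diseases.
#' @export
build_label_matrix <- function(assoc, herb_ids, categories) {
  unknown <- setdiff(unique(assoc$disease), categories)
  if (length(unknown)) {
    stop("unknown disease categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  Y <- matrix(0L, length(herb_ids), length(categories),
              dimnames = list(herb_ids, categories))
  keep <- assoc$herb_id %in% herb_ids
  if (any(keep)) {
    Y[cbind(match(assoc$herb_id[keep], herb_ids),
            match(assoc$disease[keep], categories))] <- 1L
  }
  Y
}

#' Sample a balanced positive/negative link dataset with splits
#'
#' All edges of `A` become positives; an equal number of non-edges
#' (excluding self-pairs) are sampled uniformly as negatives. Each class is
#' split 60/20/20 into train/validation/test (train gets
#' `floor(0.6 m)`, validation `floor(0.2 m)`, test the remainder).
#'
#' @param A Adjacency matrix.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @param fractions Length-3 split fractions summing to 1.
#' @return A data.frame with columns `i`, `j` (row/col indices, `i < j`),
#'   `label` (1/0) and `split` (`train`/`val`/`test`).
#' @export
sample_links <- function(A, seed, fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  pos <- ut[A[ut] == 1, , drop = FALSE]
  neg_pool <- ut[A[ut] == 0, , drop = FALSE]
  m <- nrow(pos)
  if (m < 5) stop("need at least 5 positive edges to split")
  if (nrow(neg_pool) < m) {
    stop("graph too dense: not enough non-edges to match positives")
  }
  with_seed(seed, {
    neg <- neg_pool[sample(nrow(neg_pool), m), , drop = FALSE]
    assign_split <- function(k) {
      n_tr <- floor(fractions[1] * k)
      n_va <- floor(fractions[2] * k)
      sample(c(rep("train", n_tr), rep("val", n_va),
               rep("test", k - n_tr - n_va)))
    }
    out <- rbind(
      data.frame(i = pos[, 1], j = pos[, 2], label = 1L,
                 split = assign_split(m), stringsAsFactors = FALSE),
      data.frame(i = neg[, 1], j = neg[, 2], label = 0L,
                 split = assign_split(m), stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    out
  })
}

#' Stratified 60/20/20 node split masks
#'
#' @param n Number of nodes.
#' @param seed Integer seed.
#' @param fractions Split fractions.
#' @return A list of logical masks `train`, `val`, `test`.
#' @export
sample_node_split <- function(n, seed, fractions = c(0.6, 0.2, 0.2)) {
  with_seed(seed, {
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    lab <- sample(c(rep("train", n_tr), rep("val", n_va),
                    rep("test", n - n_tr - n_va)))
    list(train = lab == "train", val = lab == "val", test = lab == "test")
  })
}
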