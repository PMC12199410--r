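#' Filter a DEG table into a signature gene set
#'
#' Herb-mode uses non-strict thresholds (|log2FC| >= `lfc_min`, p <=
#' `p_max`); formula-mode (`strict = TRUE`) uses strict inequalities
#' (|log2FC| > `lfc_min`, p < `p_max`) on the adjusted p-value, matching
#' the two filtering conventions used for single-herb perturbation series
#' and for a formula's own differential-expression contrast.
#'
#' @param deg Data.frame with columns `gene`, `log2fc`, `pvalue` and
#'   optionally `adj_pvalue`.
#' @param lfc_min Absolute log2 fold-change threshold.
#' @param p_max P-value threshold.
#' @param use_adjusted Filter on `adj_pvalue` instead of `pvalue`.
#' @param strict Use strict inequalities on both thresholds.
#' @return Character vector of gene IDs, with attributes `lfc_min`,
#'   `p_max`, `use_adjusted`, `strict`.
#' @export
filter_signature_genes <- function(deg, lfc_min = 0.5, p_max = 0.05,
                                   use_adjusted = FALSE, strict = FALSE) {
  if (use_adjusted && !"adj_pvalue" %in% names(deg)) {
    stop("missing column 'adj_pvalue' (required when use_adjusted = TRUE)")
  }
  if (nrow(deg) == 0) {
    return(structure(character(), lfc_min = lfc_min, p_max = p_max,
                     use_adjusted = use_adjusted, strict = strict))
  }
  p <- if (use_adjusted) deg$adj_pvalue else deg$pvalue
  keep <- if (strict) {
    abs(deg$log2fc) > lfc_min & p < p_max
  } else {
    abs(deg$log2fc) >= lfc_min & p <= p_max
  }
  structure(deg$gene[keep], lfc_min = lfc_min, p_max = p_max,
            use_adjusted = use_adjusted, strict = strict)
}

#' Per-tissue mean expression of a signature gene set
#'
#' Expression values strictly greater than `cap` (default 1000 nTPM) are
#' treated as extreme and excluded before averaging; a value of exactly
#' `cap` is retained. Means are taken per tissue over the remaining
#' (gene, tissue) entries.
#'
#' @param signature_genes Character vector of gene IDs.
#' @param expr Gene x tissue nonnegative expression matrix with rownames.
#' @param cap Exclusion threshold.
#' @return Named numeric vector of per-tissue means.
#' @export
aggregate_tissue_expression <- function(signature_genes, expr, cap = 1000) {
  genes <- intersect(signature_genes, rownames(expr))
  if (!length(genes)) {
    stop("empty overlap between signature genes and expression matrix rows")
  }
  sub <- expr[genes, , drop = FALSE]
  sub[sub > cap] <- NA_real_
  colMeans(sub, na.rm = TRUE)
}

#' Read a meridian-to-tissue map
#'
#' The package ships a default map of the ten organ meridians to
#' anatomical tissues (the two non-organ meridians have no tissue
#' analogue) as an editable TSV: columns `meridian` and `tissues`
#' (semicolon-delimited).
#'
#' @param path TSV path; defaults to the shipped map.
#' @return Named list meridian -> character vector of tissue names.
#' @export
read_meridian_map <- function(path = system.file("extdata",
                                                 "meridian_tissue_map.tsv",
                                                 package = "herbnet")) {
  df <- read_table(path, c(meridian = "character", tissues = "character"))
  setNames(lapply(df$tissues, split_multi), df$meridian)
}

#' Meridian-tissue expression alignment with a permutation test
#'
#' For each meridian of interest this computes (a) a top-k flag: does any
#' of its mapped tissues rank within the top `top_k` tissues by mean
#' signature-gene expression; and (b) a permutation p-value: the
#' probability that a random gene set of the same size yields a mean
#' expression over the mapped tissues at least as high as the signature
#' set's. The herb-level alignment flag is true when any meridian reaches
#' permutation p <= 0.05.
#'
#' @param signature_genes Character vector of gene IDs.
#' @param expr Gene x tissue expression matrix.
#' @param meridian_map Named list: meridian -> character vector of tissue
#'   column names.
#' @param top_k Rank threshold (default 10).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param cap Extreme-value exclusion threshold passed to
#'   [aggregate_tissue_expression()].
#' @return A list with `tissue_means`, `tissue_ranks` (1 = highest mean),
#'   `per_meridian` (data.frame `meridian`, `top_k_flag`, `perm_p`,
#'   `observed`), and `aligned` (logical herb-level flag).
#' @export
meridian_alignment <- function(signature_genes, expr, meridian_map,
                               top_k = 10, n_perm = 1000, seed = 1,
                               cap = 1000) {
  if (top_k > ncol(expr)) {
    stop("top_k exceeds the number of tissues")
  }
  missing_t <- setdiff(unlist(meridian_map), colnames(expr))
  if (length(missing_t)) {
    stop("meridian map references unknown tissue(s): ",
         paste(missing_t, collapse = ", "))
  }
  means <- aggregate_tissue_expression(signature_genes, expr, cap = cap)
  ranks <- rank(-means, ties.method = "first")
  genes <- intersect(signature_genes, rownames(expr))
  n_sig <- length(genes)

  expr_capped <- expr
  expr_capped[expr_capped > cap] <- NA_real_

  per <- with_seed(seed, {
    do.call(rbind, lapply(names(meridian_map), function(m) {
      tset <- meridian_map[[m]]
      # per-gene mean over the meridian's mapped tissues
      u <- rowMeans(expr_capped[, tset, drop = FALSE], na.rm = TRUE)
      obs <- mean(u[genes], na.rm = TRUE)
      idx <- matrix(sample.int(nrow(expr), n_sig * n_perm, replace = TRUE),
                    nrow = n_sig)
      null_means <- colMeans(matrix(u[idx], nrow = n_sig), na.rm = TRUE)
      p <- (1 + sum(null_means >= obs)) / (n_perm + 1)
      data.frame(meridian = m,
                 top_k_flag = any(ranks[tset] <= top_k),
                 perm_p = p, observed = obs,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(per) <- NULL
  list(tissue_means = means, tissue_ranks = ranks, per_meridian = per,
       aligned = any(per$perm_p <= 0.05))
}
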