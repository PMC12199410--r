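# Perturbation-weighted PPI proximity: edge weights derive from the
# averaged |log2FC| of the incident genes, shortest-path distances link
# signature genes to ingredient targets, the top 5% smallest distances are
# flagged as significant associations, and theory groups (herb, nature,
# flavor, meridian) are compared by Fisher exact tests on flag counts and
# Welch t-tests on distances.

#' Build the perturbation-weighted PPI network
#'
#' Edge weights derive from the mean absolute log2 fold change of the two
#' incident genes, `m = (|lfc_u| + |lfc_v|) / 2`:
#' `literal-mean-abs` uses `w = m` (the wording of the weighting rule taken
#' literally, under which shortest paths avoid perturbed genes);
#' `inverse` uses `w = 1 / (1 + m)` and `exp-decay` uses `w = exp(-m)`,
#' under both of which strongly perturbed neighborhoods become short —
#' the reading consistent with interpreting small distances as strong
#' association. Genes without a measured log2FC are imputed 0. Topology is
#' unchanged.
#'
#' @param ppi An igraph (undirected, simple) or a two-column edge
#'   data.frame.
#' @param perturbation Named numeric vector of log2FC per gene.
#' @param transform `"literal-mean-abs"`, `"inverse"` or `"exp-decay"`.
#' @param signed Average signed log2FC instead of absolute values.
#' @return An igraph with a `weight` edge attribute and graph attributes
#'   `transform` and `weighting_note` recording the ambiguity.
#' @export
build_weighted_ppi <- function(ppi, perturbation,
                               transform = c("literal-mean-abs", "inverse",
                                             "exp-decay"),
                               signed = FALSE) {
  transform <- match.arg(transform)
  g <- if (igraph::is_igraph(ppi)) ppi else
    igraph::graph_from_data_frame(ppi[, 1:2], directed = FALSE)
  g <- igraph::simplify(g)
  genes <- igraph::V(g)$name
  lfc <- setNames(rep(0, length(genes)), genes)
  known <- intersect(genes, names(perturbation))
  lfc[known] <- perturbation[known]
  if (!signed) lfc <- abs(lfc)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  m <- (abs(lfc[ends[, 1]]) + abs(lfc[ends[, 2]])) / 2
  w <- switch(transform,
              "literal-mean-abs" = m,
              "inverse" = 1 / (1 + m),
              "exp-decay" = exp(-m))
  igraph::E(g)$weight <- as.numeric(w)
  g <- igraph::set_graph_attr(g, "transform", transform)
  igraph::set_graph_attr(
    g, "weighting_note",
    paste("edge weight = averaged |log2FC| of incident genes;",
          "under 'literal-mean-abs' shortest paths penalize perturbed",
          "edges, under 'inverse'/'exp-decay' they prefer them"))
}

#' Weighted shortest-path distance between two genes
#'
#' Minimum over all paths of the summed edge weights (Dijkstra;
#' nonnegative weights). Disconnected pairs return `Inf`.
#'
#' @param B Weighted PPI from [build_weighted_ppi()].
#' @param i,j Gene names.
#' @return Numeric distance.
#' @export
shortest_distance <- function(B, i, j) {
  missing_g <- setdiff(c(i, j), igraph::V(B)$name)
  if (length(missing_g)) {
    stop("gene(s) absent from network: ", paste(missing_g, collapse = ", "))
  }
  as.numeric(igraph::distances(B, v = i, to = j,
                               weights = igraph::E(B)$weight,
                               algorithm = "dijkstra"))
}

#' Signature-gene x target distance matrix
#'
#' One single-source Dijkstra run per row gene. Genes absent from the
#' network are dropped and reported in the `dropped` attribute;
#' disconnected pairs carry `Inf`.
#'
#' @param B Weighted PPI.
#' @param signature_genes Row gene IDs.
#' @param cols Column gene IDs (targets or disease genes).
#' @return Numeric matrix with `dropped` attribute (list of dropped row /
#'   column genes).
#' @export
distance_matrix <- function(B, signature_genes, cols) {
  genes <- igraph::V(B)$name
  rows_in <- intersect(unique(signature_genes), genes)
  cols_in <- intersect(unique(cols), genes)
  if (!length(rows_in)) stop("empty overlap: no signature gene in network")
  if (!length(cols_in)) stop("empty overlap: no column gene in network")
  C <- igraph::distances(B, v = rows_in, to = cols_in,
                         weights = igraph::E(B)$weight,
                         algorithm = "dijkstra")
  attr(C, "dropped") <- list(rows = setdiff(unique(signature_genes), rows_in),
                             cols = setdiff(unique(cols), cols_in))
  C
}

#' Flag the top fraction of shortest distances as significant
#'
#' Global scope: the `floor(fraction * m)` smallest of the `m` finite
#' entries are flagged, ties at the cutoff broken by row-then-column
#' index. Per-column scope applies the same rule within each column.
#'
#' @param C Distance matrix.
#' @param fraction Fraction flagged (default 0.05).
#' @param scope `"global"` or `"per-column"`.
#' @return Logical matrix, same shape as `C`, with attribute `fraction`.
#' @export
flag_top_fraction <- function(C, fraction = 0.05,
                              scope = c("global", "per-column")) {
  scope <- match.arg(scope)
  flags <- matrix(FALSE, nrow(C), ncol(C), dimnames = dimnames(C))
  flag_block <- function(vals, rows, cols) {
    fin <- is.finite(vals)
    k <- floor(fraction * sum(fin))
    sel <- logical(length(vals))
    if (k > 0) {
      o <- order(vals, rows, cols, na.last = TRUE)
      o <- o[fin[o]]
      sel[o[seq_len(k)]] <- TRUE
    }
    sel
  }
  if (!any(is.finite(C))) stop("no finite distances to flag")
  if (scope == "global") {
    rows <- rep(seq_len(nrow(C)), times = ncol(C))
    cols <- rep(seq_len(ncol(C)), each = nrow(C))
    flags[] <- flag_block(as.vector(C), rows, cols)
  } else {
    for (j in seq_len(ncol(C))) {
      flags[, j] <- flag_block(C[, j], seq_len(nrow(C)),
                               rep(j, nrow(C)))
    }
  }
  attr(flags, "fraction") <- fraction
  flags
}

#' Map targets to theory groups through their herbs
#'
#' Each target inherits the union of the natures (Qi), flavors and
#' meridians of every herb it is a target of, plus the herb identities
#' themselves; targets reached through several herbs carry all their
#' groups.
#'
#' @param targets Data.frame `herb`, `ingredient`, `target`, `score`.
#' @param herb_theory Data.frame mapping formula herbs to theory labels:
#'   columns `herb`, `qi`, `flavors`, `meridians` (semicolon-delimited).
#' @param score_min Retain only ingredient-target pairs with
#'   `score > score_min` (default 700).
#' @return Named list target -> character vector of group labels
#'   (`herb:`, `qi:`, `flavor:`, `meridian:`-prefixed).
#' @export
map_targets_to_theory_groups <- function(targets, herb_theory,
                                         score_min = 700) {
  orphan <- setdiff(unique(targets$herb), herb_theory$herb)
  if (length(orphan)) {
    stop("mapping gap: targets reference unknown herb(s): ",
         paste(orphan, collapse = ", "))
  }
  kept <- targets[targets$score > score_min, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(kept))) {
    h <- kept$herb[r]
    hi <- match(h, herb_theory$herb)
    labs <- c(paste0("herb:", h),
              paste0("qi:", split_multi(herb_theory$qi[hi])),
              paste0("flavor:", split_multi(herb_theory$flavors[hi])),
              paste0("meridian:", split_multi(herb_theory$meridians[hi])))
    tg <- kept$target[r]
    out[[tg]] <- union(out[[tg]] %||% character(), labs)
  }
  out
}

#' Fisher exact enrichment of significant flags in a theory group
#'
#' 2x2 table over (signature gene, target) pairs: membership of the
#' target's group in `group` x flagged-or-not; two-sided Fisher exact test
#' (hypergeometric).
#'
#' @param flags Flag matrix from [flag_top_fraction()] (columns = targets).
#' @param groups Target-to-groups list from
#'   [map_targets_to_theory_groups()].
#' @param group Group label to test (e.g. `"herb:FH01"`).
#' @return List with `table` (2x2), `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(flags, groups, group) {
  tg <- colnames(flags)
  in_group <- vapply(tg, function(t) group %in% (groups[[t]] %||%
                                                   character()), logical(1))
  if (!any(in_group)) stop("group is empty: ", group)
  if (all(in_group)) stop("group complement is empty: ", group)
  a <- sum(flags[, in_group])
  b <- sum(!flags[, in_group])
  c_ <- sum(flags[, !in_group])
  d <- sum(!flags[, !in_group])
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("in_group", "out_group"),
                                c("flagged", "not_flagged")))
  if (a + c_ == 0 || b + d == 0) {
    warning("degenerate margin: all pairs flagged or none; p set to 1")
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  }
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Welch t-tests of group distances against a reference group
#'
#' Pools each group's finite target-signature distances and compares them
#' with the reference group's by Welch's two-sample t-test.
#'
#' @param C Distance matrix (columns = targets).
#' @param groups Target-to-groups list.
#' @param reference Reference group label.
#' @param compare Group labels to test (default: all present except the
#'   reference).
#' @return Data.frame `group`, `n`, `mean`, `median`, `t`, `p` (reference
#'   row has `t = 0`, `p = 1`).
#' @export
compare_group_distances <- function(C, groups, reference, compare = NULL) {
  all_groups <- sort(unique(unlist(groups)))
  if (!reference %in% all_groups) stop("unknown reference group: ", reference)
  compare <- compare %||% setdiff(all_groups, reference)
  group_vals <- function(g) {
    tg <- names(groups)[vapply(groups, function(x) g %in% x, logical(1))]
    tg <- intersect(tg, colnames(C))
    v <- as.vector(C[, tg, drop = FALSE])
    v[is.finite(v)]
  }
  ref <- group_vals(reference)
  rows <- lapply(c(reference, compare), function(g) {
    v <- group_vals(g)
    if (length(v) < 2) {
      warning("group skipped (needs >= 2 finite distances): ", g)
      return(NULL)
    }
    if (g == reference) {
      tt <- list(statistic = 0, p.value = 1)
    } else if (isTRUE(all.equal(sort(v), sort(ref))) &&
               length(v) == length(ref) && sd(v) == 0 && sd(ref) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(v, ref)
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               median = median(v), t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-target proximity contribution summaries
#'
#' Mean and median distance of a target to all signature genes (finite
#' entries only) plus its significant-flag count; small mean distance =
#' large contribution to the perturbation.
#'
#' @param C Distance matrix.
#' @param flags Optional flag matrix.
#' @param target Single target column name, or `NULL` for all targets
#'   ranked by ascending mean distance.
#' @return Data.frame `target`, `n_finite`, `mean`, `median`, `n_flagged`.
#' @export
target_contribution <- function(C, flags = NULL, target = NULL) {
  cols <- target %||% colnames(C)
  missing_t <- setdiff(cols, colnames(C))
  if (length(missing_t)) stop("unknown target column: ",
                              paste(missing_t, collapse = ", "))
  rows <- lapply(cols, function(tg) {
    v <- C[, tg]
    fin <- v[is.finite(v)]
    if (!length(fin)) stop("target unreachable from every signature gene: ",
                           tg)
    data.frame(target = tg, n_finite = length(fin), mean = mean(fin),
               median = median(fin),
               n_flagged = if (is.null(flags)) NA_integer_ else
                 sum(flags[, tg]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean, out$target), ]
  rownames(out) <- NULL
  out
}
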