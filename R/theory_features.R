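split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, ";", fixed = TRUE)[[1]]
}

# Per-herb character vectors of category-prefixed property labels.
# (paste0 pads a zero-length vector to "", hence the explicit guard.)
prefix_labels <- function(prefix, x) {
  v <- split_multi(x)
  if (length(v)) paste0(prefix, v) else character()
}

herb_property_sets <- function(herbs) {
  lapply(seq_len(nrow(herbs)), function(i) {
    c(prefix_labels("qi:", herbs$qi[i]),
      prefix_labels("flavor:", herbs$flavors[i]),
      prefix_labels("meridian:", herbs$meridians[i]),
      prefix_labels("syndrome:", herbs$syndromes[i]))
  })
}

#' Build the property vocabulary observed in a herb table
#'
#' The vocabulary is the union of all (category, label) pairs observed
#' across the four theory categories (Qi, Flavor, Meridian, syndrome),
#' sorted by category then label so the feature column order is stable
#' across runs. Column names are category-prefixed (`meridian:lung`) so
#' identically named labels in different categories cannot collide.
#'
#' @param herbs Herb table (columns `herb_id`, `qi`, `flavors`, `meridians`,
#'   `syndromes`; multi-labels semicolon-delimited).
#' @return A data.frame with columns `category`, `label`, `label_full`,
#'   attribute `f` = total vocabulary size.
#' @export
build_vocabulary <- function(herbs) {
  if (nrow(herbs) == 0) stop("empty herb table: no features to build")
  cats <- list(qi = herbs$qi, flavor = herbs$flavors,
               meridian = herbs$meridians, syndrome = herbs$syndromes)
  rows <- lapply(names(cats), function(cat) {
    labs <- sort(unique(unlist(lapply(cats[[cat]], split_multi))))
    if (!length(labs)) return(NULL)
    data.frame(category = cat, label = labs,
               label_full = paste0(cat, ":", labs),
               stringsAsFactors = FALSE)
  })
  vocab <- do.call(rbind, rows)
  vocab <- vocab[order(match(vocab$category,
                             c("qi", "flavor", "meridian", "syndrome")),
                       vocab$label), ]
  rownames(vocab) <- NULL
  attr(vocab, "f") <- nrow(vocab)
  vocab
}

#' One-hot encode herbs against a property vocabulary
#'
#' @param herbs Herb table.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @return A binary matrix, rows = herbs (named by `herb_id`, in table
#'   order), columns = `label_full` vocabulary entries.
#' @export
encode_one_hot <- function(herbs, vocab) {
  X <- matrix(0L, nrow(herbs), nrow(vocab),
              dimnames = list(herbs$herb_id, vocab$label_full))
  props <- herb_property_sets(herbs)
  for (i in seq_along(props)) {
    unknown <- setdiff(props[[i]], vocab$label_full)
    if (length(unknown)) {
      stop(sprintf("vocabulary mismatch: herb %s carries unknown label(s) %s",
                   herbs$herb_id[i], paste(unknown, collapse = ", ")))
    }
    X[i, props[[i]]] <- 1L
  }
  X
}
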