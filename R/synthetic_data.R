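#' Simulation configuration for the synthetic study
#'
#' Collects every knob of the synthetic-data generator: herb property
#' vocabularies, prescription corpus structure, herb-disease label coupling,
#' the perturbed interactome, and meridian-aligned tissue expression. The
#' defaults define the study conditions the pipeline is exercised under;
#' `seed` fully determines every generated table.
#'
#' @param n_herbs Number of herbs.
#' @param qi_levels,flavor_levels,meridian_levels,syndrome_levels Property
#'   vocabularies (character vectors). Defaults: 4 Qi, 5 Flavors, 12
#'   Meridians, 37 syndromes.
#' @param n_diseases Number of disease categories (default 14).
#' @param n_prescriptions Number of prescriptions in the corpus.
#' @param herbs_per_prescription Integer range (length-2) of herbs drawn per
#'   prescription.
#' @param synergy_blocks List of integer vectors partitioning a subset of
#'   herb indices into co-prescribed blocks, or `NULL` for none.
#' @param block_boost Multiplier by which within-block herb pairs are
#'   over-sampled relative to cross-block pairs.
#' @param property_homophily Log-linear preference for co-prescribing
#'   herbs that share theory properties with the prescription's seed herb
#'   (herbs in one formula tend to share theory roles); 0 disables.
#' @param label_coupling Log-odds per shared planted property linking theory
#'   properties to disease labels.
#' @param props_per_disease Number of planted properties per disease.
#' @param n_genes,n_signature_genes Interactome size and signature-set size.
#' @param ppi_model `"scale-free"` or `"erdos-renyi"`.
#' @param ppi_m Edges added per vertex (scale-free) / expected degree basis.
#' @param perturb_hops Radius (hops) of the perturbed neighborhood around
#'   the signature genes.
#' @param perturb_effect Mean |log2FC| planted inside the perturbed
#'   neighborhood.
#' @param noise_sd Gaussian noise SD added to every gene's log2FC.
#' @param n_formula_herbs Herbs in the studied formula (default 9).
#' @param targets_per_herb Targets drawn per formula herb.
#' @param n_tissues Number of tissues in the expression matrix (default 54).
#' @param meridian_effect nTPM elevation of a herb's signature genes in
#'   tissues mapped to that herb's meridians.
#' @param seed Master seed; every generator derives its own substream from
#'   it by a fixed offset.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_herbs = 60,
                       qi_levels = paste0("qi", 1:4),
                       flavor_levels = paste0("flavor", 1:5),
                       meridian_levels = paste0("meridian", 1:12),
                       syndrome_levels = paste0("syndrome", 1:37),
                       n_diseases = 14,
                       n_prescriptions = 2000,
                       herbs_per_prescription = c(4L, 6L),
                       synergy_blocks = NULL,
                       block_boost = 1,
                       property_homophily = 6,
                       label_coupling = 0,
                       props_per_disease = 3,
                       n_genes = 1000,
                       n_signature_genes = 30,
                       ppi_model = c("scale-free", "erdos-renyi"),
                       ppi_m = 2,
                       perturb_hops = 1,
                       perturb_effect = 0,
                       noise_sd = 0,
                       n_formula_herbs = 9,
                       targets_per_herb = 25,
                       n_tissues = 54,
                       meridian_effect = 0,
                       seed = 1L) {
  ppi_model <- match.arg(ppi_model)
  counts <- c(n_herbs = n_herbs, n_diseases = n_diseases,
              n_prescriptions = n_prescriptions, n_genes = n_genes,
              n_signature_genes = n_signature_genes, n_tissues = n_tissues,
              n_formula_herbs = n_formula_herbs,
              targets_per_herb = targets_per_herb)
  if (any(counts < 0)) {
    stop("all counts must be >= 0: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (!is.null(synergy_blocks)) {
    idx <- unlist(synergy_blocks)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > n_herbs)) {
      stop("synergy_blocks must partition a subset of 1..n_herbs exactly once")
    }
  }
  if (length(herbs_per_prescription) != 2 ||
      herbs_per_prescription[1] > herbs_per_prescription[2]) {
    stop("herbs_per_prescription must be an increasing length-2 range")
  }
  cfg <- list(
    n_herbs = as.integer(n_herbs), qi_levels = qi_levels,
    flavor_levels = flavor_levels, meridian_levels = meridian_levels,
    syndrome_levels = syndrome_levels, n_diseases = as.integer(n_diseases),
    n_prescriptions = as.integer(n_prescriptions),
    herbs_per_prescription = as.integer(herbs_per_prescription),
    synergy_blocks = synergy_blocks, block_boost = block_boost,
    property_homophily = property_homophily,
    label_coupling = label_coupling,
    props_per_disease = as.integer(props_per_disease),
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    ppi_model = ppi_model, ppi_m = ppi_m,
    perturb_hops = as.integer(perturb_hops),
    perturb_effect = perturb_effect, noise_sd = noise_sd,
    n_formula_herbs = as.integer(n_formula_herbs),
    targets_per_herb = as.integer(targets_per_herb),
    n_tissues = as.integer(n_tissues), meridian_effect = meridian_effect,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic herb theory table
#'
#' Each herb receives exactly one Qi, 1-2 Flavors, 1-3 Meridians and 0-3
#' syndromes, sampled uniformly from the configured vocabularies.
#' Multi-label columns are semicolon-delimited strings.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `herb_id`, `name`, `qi`, `flavors`,
#'   `meridians`, `syndromes`.
#' @export
generate_herb_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_herbs
  if (n == 0) {
    return(data.frame(herb_id = character(), name = character(),
                      qi = character(), flavors = character(),
                      meridians = character(), syndromes = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(sub_seed(config$seed, "herbs"), {
    pick <- function(levels, k) {
      paste(sort(sample(levels, k)), collapse = ";")
    }
    qi <- sample(config$qi_levels, n, replace = TRUE)
    flavors <- vapply(sample(1:2, n, replace = TRUE),
                      function(k) pick(config$flavor_levels, k), character(1))
    meridians <- vapply(sample(1:3, n, replace = TRUE),
                        function(k) pick(config$meridian_levels, k),
                        character(1))
    syndromes <- vapply(sample(0:3, n, replace = TRUE),
                        function(k) if (k == 0) "" else
                          pick(config$syndrome_levels, k), character(1))
    data.frame(
      herb_id = sprintf("H%03d", seq_len(n)),
      name = sprintf("herb_%03d", seq_len(n)),
      qi = qi, flavors = flavors, meridians = meridians,
      syndromes = syndromes, stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic prescription corpus
#'
#' Prescriptions are herb-ID sets. Each prescription starts from a
#' uniformly chosen seed herb; further herbs are drawn with probability
#' proportional to `exp(property_homophily * shared / max_shared)` where
#' `shared` counts theory properties in common with the seed herb, so
#' co-prescribed herbs share theory roles the way real formulas do. When
#' `synergy_blocks` are configured, a prescription instead seeds from a
#' block with probability governed by `block_boost`, drawing most of its
#' herbs from that block, so within-block pairs co-occur roughly
#' `block_boost` times more often than cross-block pairs.
#'
#' @param config A [sim_config()].
#' @param herbs Herb table from [generate_herb_table()].
#' @return A list of character vectors of herb IDs (class
#'   `prescription_corpus`).
#' @export
generate_prescriptions <- function(config, herbs) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_prescriptions > 0 && nrow(herbs) == 0) {
    stop("cannot generate prescriptions from an empty herb table")
  }
  if (config$n_prescriptions == 0) {
    return(structure(list(), class = "prescription_corpus"))
  }
  n <- nrow(herbs)
  blocks <- config$synergy_blocks
  rng <- config$herbs_per_prescription
  # shared-property counts, scaled to [0, 1], drive homophilous sampling
  sim <- NULL
  if (config$property_homophily > 0 && n > 1) {
    P <- encode_one_hot(herbs, build_vocabulary(herbs))
    sim <- P %*% t(P)
    mx <- max(sim[upper.tri(sim)], 1)
    sim <- sim / mx
  }
  with_seed(sub_seed(config$seed, "prescriptions"), {
    out <- vector("list", config$n_prescriptions)
    for (p in seq_len(config$n_prescriptions)) {
      size <- min(n, sample(seq(rng[1], rng[2]), 1))
      if (!is.null(blocks) && config$block_boost > 1 &&
          runif(1) < config$block_boost / (config$block_boost + 1)) {
        b <- blocks[[sample(length(blocks), 1)]]
        k_block <- min(length(b), size)
        idx <- sample(b, k_block)
        if (size > k_block) {
          rest <- setdiff(seq_len(n), idx)
          idx <- c(idx, sample(rest, size - k_block))
        }
      } else if (!is.null(sim)) {
        s0 <- sample(n, 1)
        rest <- setdiff(seq_len(n), s0)
        w <- exp(config$property_homophily * sim[s0, rest])
        idx <- c(s0, rest[sample.int(length(rest), size - 1, prob = w)])
      } else {
        idx <- sample(n, size)
      }
      out[[p]] <- sort(herbs$herb_id[idx])
    }
    structure(out, class = "prescription_corpus")
  })
}

#' Generate synthetic herb-disease associations
#'
#' Each disease plants a small set of theory properties; a herb is
#' associated with the disease with probability
#' `plogis(label_coupling * (2 * overlap - 1))`, where `overlap` is the
#' number of planted properties the herb carries. At `label_coupling = 0`
#' every probability is exactly 0.5; at strong coupling, herbs carrying
#' any planted property are almost surely associated while the rest
#' almost surely are not.
#'
#' @param config A [sim_config()].
#' @param herbs Herb table from [generate_herb_table()].
#' @return A list with `assoc` (data.frame `herb_id`, `disease`),
#'   `diseases` (ordered category vector) and `planted` (per-disease
#'   planted property labels).
#' @export
generate_disease_labels <- function(config, herbs) {
  stopifnot(inherits(config, "sim_config"), config$n_diseases >= 1)
  diseases <- sprintf("D%02d", seq_len(config$n_diseases))
  vocab <- build_vocabulary(herbs)
  props <- herb_property_sets(herbs)
  with_seed(sub_seed(config$seed, "labels"), {
    planted <- lapply(diseases, function(d) {
      sample(vocab$label_full, min(config$props_per_disease,
                                   length(vocab$label_full)))
    })
    names(planted) <- diseases
    rows <- list()
    for (d in diseases) {
      overlap <- vapply(props, function(p) sum(planted[[d]] %in% p),
                        numeric(1))
      pr <- plogis(config$label_coupling * (2 * overlap - 1))
      hit <- runif(nrow(herbs)) < pr
      if (any(hit)) {
        rows[[d]] <- data.frame(herb_id = herbs$herb_id[hit], disease = d,
                                stringsAsFactors = FALSE)
      }
    }
    assoc <- if (length(rows)) do.call(rbind, rows) else
      data.frame(herb_id = character(), disease = character(),
                 stringsAsFactors = FALSE)
    rownames(assoc) <- NULL
    list(assoc = assoc, diseases = diseases, planted = planted)
  })
}

#' Probability of association under the label-coupling model
#'
#' Closed-form logistic link used by [generate_disease_labels()]; exposed
#' so tests can compare empirical rates against it.
#'
#' @param overlap Number of planted properties a herb shares with a disease.
#' @param coupling The `label_coupling` effect size.
#' @return Association probability.
#' @export
label_coupling_probability <- function(overlap, coupling) {
  plogis(coupling * (2 * overlap - 1))
}

#' Generate a perturbed interactome with planted principal-herb structure
#'
#' Builds a connected PPI graph, picks a localized signature gene set (a
#' breadth-first cluster around a random origin gene), and plants a
#' perturbation: genes within `perturb_hops` hops of any signature gene get
#' |log2FC| centred on `perturb_effect` (random sign), all genes get
#' Gaussian noise of SD `noise_sd`. A designated principal herb (the first
#' formula herb) draws its targets from inside the perturbed neighborhood;
#' the remaining herbs draw uniformly. Ingredient-target scores for planted
#' pairs exceed the conventional confidence threshold of 700.
#'
#' @param config A [sim_config()].
#' @return A list with `ppi` (igraph), `perturbation` (named numeric
#'   log2FC per gene), `signature_genes` (character), `targets` (data.frame
#'   `herb`, `ingredient`, `target`, `score`), `herb_ingredients`
#'   (data.frame `herb`, `ingredient`), `principal_herb`, and
#'   `perturbed_genes`.
#' @export
generate_ppi_with_perturbation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes <= config$n_signature_genes) {
    stop("n_genes must exceed n_signature_genes")
  }
  if (config$n_genes < 2) stop("cannot form a connected graph with < 2 genes")
  with_seed(sub_seed(config$seed, "ppi"), {
    g <- if (config$ppi_model == "scale-free") {
      igraph::sample_pa(config$n_genes, m = config$ppi_m, directed = FALSE)
    } else {
      g0 <- igraph::sample_gnm(config$n_genes,
                               m = config$ppi_m * config$n_genes)
      comp <- igraph::components(g0)
      while (comp$no > 1) {
        anchors <- vapply(seq_len(comp$no),
                          function(k) which(comp$membership == k)[1],
                          integer(1))
        g0 <- igraph::add_edges(g0, rbind(anchors[-length(anchors)],
                                          anchors[-1]))
        comp <- igraph::components(g0)
      }
      igraph::simplify(g0)
    }
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    igraph::V(g)$name <- genes

    origin <- sample(config$n_genes, 1)
    bfs_order <- igraph::bfs(g, root = origin, order = TRUE)$order
    sig <- genes[as.integer(bfs_order)[seq_len(config$n_signature_genes)]]

    ball <- igraph::ego(g, order = config$perturb_hops, nodes = sig)
    perturbed <- unique(unlist(lapply(ball, function(v) v$name)))

    lfc <- rnorm(config$n_genes, 0, config$noise_sd)
    names(lfc) <- genes
    if (config$perturb_effect > 0) {
      signs <- sample(c(-1, 1), length(perturbed), replace = TRUE)
      lfc[perturbed] <- lfc[perturbed] + signs * config$perturb_effect
    }

    herbs <- sprintf("FH%02d", seq_len(config$n_formula_herbs))
    principal <- herbs[1]
    rows <- list()
    ing_rows <- list()
    for (h in herbs) {
      n_ing <- 3L
      ings <- sprintf("%s_ing%d", h, seq_len(n_ing))
      ing_rows[[h]] <- data.frame(herb = h, ingredient = ings,
                                  stringsAsFactors = FALSE)
      pool <- if (h == principal) perturbed else genes
      tg <- sample(pool, min(config$targets_per_herb, length(pool)))
      rows[[h]] <- data.frame(
        herb = h,
        ingredient = sample(ings, length(tg), replace = TRUE),
        target = tg,
        score = round(runif(length(tg), 701, 999)),
        stringsAsFactors = FALSE
      )
    }
    targets <- do.call(rbind, rows)
    rownames(targets) <- NULL
    herb_ingredients <- do.call(rbind, ing_rows)
    rownames(herb_ingredients) <- NULL
    list(ppi = g, perturbation = lfc, signature_genes = sig,
         targets = targets, herb_ingredients = herb_ingredients,
         principal_herb = principal, perturbed_genes = perturbed)
  })
}

#' Generate meridian-aligned tissue expression and a DEG table
#'
#' Baseline nTPM values are Gamma-distributed; the signature genes of the
#' supplied herb gain `meridian_effect` nTPM in every tissue mapped to one
#' of the herb's meridians. The DEG table is generated so that exactly the
#' signature genes satisfy |log2FC| >= 0.5 and p <= 0.05.
#'
#' @param config A [sim_config()].
#' @param herb A single row of the herb table (the herb whose meridians are
#'   planted), or `NULL` for no planted meridian.
#' @param signature_genes Character vector of signature gene IDs (subset of
#'   the generated gene universe `G0001..`).
#' @return A list with `expression` (gene x tissue matrix), `meridian_map`
#'   (list meridian -> tissue names), `deg` (data.frame `gene`, `log2fc`,
#'   `pvalue`, `adj_pvalue`).
#' @export
generate_tissue_expression <- function(config, herb = NULL,
                                       signature_genes = character()) {
  stopifnot(inherits(config, "sim_config"))
  n_mapped <- min(10L, length(config$meridian_levels))
  if (config$n_tissues < n_mapped) {
    stop("n_tissues must cover the mapped meridian tissues")
  }
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  meridian_map <- setNames(as.list(tissues[seq_len(n_mapped)]),
                           config$meridian_levels[seq_len(n_mapped)])
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  with_seed(sub_seed(config$seed, "tissue"), {
    expr <- matrix(rgamma(config$n_genes * config$n_tissues,
                          shape = 2, scale = 10),
                   nrow = config$n_genes,
                   dimnames = list(genes, tissues))
    if (!is.null(herb) && config$meridian_effect != 0 &&
        length(signature_genes)) {
      mer <- strsplit(herb$meridians, ";", fixed = TRUE)[[1]]
      mapped <- unlist(meridian_map[intersect(mer, names(meridian_map))])
      if (length(mapped)) {
        expr[signature_genes, mapped] <-
          expr[signature_genes, mapped] + config$meridian_effect
      }
    }
    is_sig <- genes %in% signature_genes
    lfc <- numeric(config$n_genes)
    pval <- numeric(config$n_genes)
    n_sig <- sum(is_sig)
    lfc[is_sig] <- sample(c(-1, 1), n_sig, TRUE) * (0.5 + abs(rnorm(n_sig)))
    pval[is_sig] <- runif(n_sig, 0, 0.05)
    lfc[!is_sig] <- runif(config$n_genes - n_sig, -0.49, 0.49)
    pval[!is_sig] <- runif(config$n_genes - n_sig, 0.051, 1)
    deg <- data.frame(gene = genes, log2fc = lfc, pvalue = pval,
                      adj_pvalue = pmin(1, stats::p.adjust(pval, "BH")),
                      stringsAsFactors = FALSE)
    list(expression = expr, meridian_map = meridian_map, deg = deg)
  })
}
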