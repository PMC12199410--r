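---
title: "Models and methods in herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

`herbnet` analyses multi-herb formulas through three connected models: a
graph attention network (GAT) for multi-label herb–disease association,
an enclosing-subgraph classifier (SEAL-style DGCNN) for herb–herb
combination prediction, and a perturbation-weighted protein–protein
interaction (PPI) proximity analysis that links herb ingredient targets
to drug-perturbation signature genes. This vignette documents the
models, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. Theory features and the herb graph

Each herb carries one thermal nature (Qi), one or two flavors, one to
three meridians and up to three syndrome indications. The vocabulary is
data-driven: `build_vocabulary()` collects exactly the (category,
label) pairs observed in the input table, sorted by category then
label, and `encode_one_hot()` produces the binary feature matrix
`X ∈ {0,1}^{n×f}`. Column names are category-prefixed
(`meridian:lung`) so labels cannot collide across categories. We do not
hard-code a property count: published descriptions of comparable
pipelines quote inconsistent totals, and the four default vocabularies
(4 Qi + 5 Flavors + 12 Meridians + 37 syndromes) give `f = 58` when
fully observed.

The herb–herb adjacency comes from prescription co-occurrence with a
**strict** threshold: an edge requires a pair to appear in *more than*
five prescriptions; a count of exactly five yields no edge. The
threshold and strictness are both arguments of `build_adjacency()` for
sensitivity analysis.

Link datasets (`sample_links()`) pair every edge with a uniformly
sampled non-edge (self-pairs excluded) and split each class
60/20/20 into train/validation/test; train receives `floor(0.6 m)`,
validation `floor(0.2 m)`, test the remainder.

## 2. The GAT herb–disease model

Two attention layers. Per head, attention logits are
`e_ij = LeakyReLU(aᵀ[W h_i ‖ W h_j])`, normalized by softmax over each
node's neighborhood (self-loops are added so isolated herbs retain
their own features). Hidden activations are LeakyReLU; the eight (by
default) heads are concatenated after layer 1 and averaged at the
output layer, which emits `c` logits per herb for a
binary-cross-entropy-with-logits loss. A widely printed form of the
attention numerator concatenates the center transform with itself,
which would make attention independent of the neighbor; we use the
standard source–neighbor concatenation.

Defaults (all in `gat_config()`): hidden width 256 split across 8
heads, output dimension 14, dropout on the features entering each
layer, Adam, up to 100 epochs with early stopping at patience 10 on
validation loss. Test metrics are computed at the parameters of the
best validation epoch, with dropout disabled (two evaluation passes are
bit-identical). The implementation is plain base R with analytic
backpropagation; the test suite verifies every gradient against
central finite differences at tolerance 1e-6.

Metric conventions are recorded in the report because they change the
numbers materially: AP is micro-averaged over the flattened
score/label matrix, ROC-AUC is macro-averaged over label columns
(single-class columns are skipped and listed), LRAP and label-ranking
loss are sample-wise, with ties handled as in the standard Python
implementations (a tied false label counts as ranked above a true
one). Frozen oracle values for a 3×3 toy were computed with that
reference implementation during development.

Baselines (`run_baseline()`): per-label logistic regression and KNN on
the raw features, and a two-layer mean-aggregation graph convolution
network — the same splits and the same metrics report.

## 3. The SEAL-style combination model

For a candidate pair, `extract_enclosing_subgraph()` induces the union
of the anchors' h-hop neighborhoods (default `hops = 1`, which keeps
subgraphs desk-scale on dense herb graphs) and **removes the target
edge** so the label never leaks into the input. Nodes receive
Double-Radius structural labels — both anchors get label 1, a node at
distances `(dx, dy)` gets `1 + min(dx,dy) + (d/2)((d/2) + d%%2 − 1)`
with `d = dx + dy`, unreachable nodes get the 0 bucket — the canonical
labeling for this architecture, which the published description leaves
unstated. Node inputs concatenate the one-hot structural label
(clamped at `label_cap`), a pretrained global embedding, and the herb's
theory features.

"Pretrained embeddings" are likewise unstated in published
descriptions; we use a deterministic random-walk factorization: the
window-averaged transition-matrix powers are shifted-log transformed
and factorized by truncated SVD — the classical closed form of
skip-gram random-walk embedding training — which removes a heavy
dependency and makes the embeddings exactly reproducible.

The DGCNN stacks degree-normalized graph convolutions
`H^{l+1}_v = σ(W^l Σ_{u∈N_v} H^l_u / √(d_v d_u))` (neighbors only, per
the stated propagation rule; zero-degree nodes receive zeros),
concatenates all layer outputs, sort-pools to `k` nodes (default: the
60th percentile of training subgraph sizes) and applies a per-node 1-D
convolution and a dense readout to produce the logit. Sort pooling
orders nodes lexicographically over the concatenated channels read
from the sort channel backwards, so the logit is invariant to any
input node permutation including ties. The loss is the standard mean
binary cross-entropy over logits; the logistic function is
`σ(x) = 1/(1+e^{−x})` (a printed form with a negated sign is a clear
erratum, since the loss requires outputs in (0,1)).

Link baselines: a two-layer GCN with an inner-product decoder, and
logistic regression on the element-wise product of the pretrained
embeddings (the random-walk baseline).

## 4. Perturbation-weighted network proximity

The PPI network is binary; genes without a measured log2FC are imputed
0 rather than dropped, preserving connectivity. Edge weights derive
from the averaged absolute log2 fold change of the incident genes,
`m_e = (|lfc_u| + |lfc_v|)/2`. Three transforms are exposed because the
natural-language description of this weighting is ambiguous in a way
that matters:

- `literal-mean-abs` (`w = m_e`): the wording taken literally. Under a
  shortest-path distance this *penalizes* perturbed edges, i.e. makes
  strongly perturbed targets look *far* from the signature.
- `inverse` (`w = 1/(1+m_e)`) and `exp-decay` (`w = exp(−m_e)`):
  perturbed neighborhoods become short, which matches the
  interpretation that small distance means strong association.

The default is the literal reading, the recovery analyses use
`inverse`, and every weighted network records the ambiguity in its
metadata. Absolute values are used in the average (a down-regulated
gene is still perturbed); signed averaging is available by flag.

`Distance(i,j)` is the minimum over paths of the summed edge weights
(Dijkstra; disconnected pairs carry `Inf`). The distance matrix `C` has
signature genes as rows and ingredient targets (retained at
interaction score strictly above 700) or disease genes as columns. The
top-5% rule flags exactly `floor(0.05·m)` of the `m` finite entries
globally (ties at the cutoff broken by row-then-column index); a
per-column variant is exposed. Disconnected pairs are excluded from
both the flag denominator and all group statistics.

Targets inherit the union of their herbs' natures, flavors and
meridians (a target reached through several herbs carries all its
groups). Enrichment per group uses a two-sided Fisher exact test on the
2×2 table (group membership × flagged), which equals the
hypergeometric-sum oracle to 1e-10 in the test suite; distance
comparisons use Welch's unequal-variance t-test (the published
description says only "t.test"; Welch is the safer default).

## 5. Meridian–tissue alignment

Signature genes come from DEG filtering with two conventions, both
exposed: non-strict (`|log2FC| ≥ threshold`, `p ≤ threshold`) for
single-herb perturbation series and strict (`>`, `<`, on the adjusted
p-value) for a formula's own contrast. Tissue aggregation excludes nTPM
values strictly greater than 1000 (exactly 1000 is retained) and
averages the remaining entries per tissue.

"Significant expression in a meridian's tissues" is operationalized two
ways, reported side by side: (a) a top-k rank flag (default k = 10) on
the mapped tissues' mean signature expression, and (b) a permutation
test — the probability that a random gene set of equal size attains a
mapped-tissue mean at least as high as the signature set's, with
`p = (1 + #{null ≥ obs})/(B + 1)`. A herb is "aligned" when any of its
meridians reaches permutation p ≤ 0.05. The meridian→tissue map ships
as data (editable): ten organ meridians mapped to their anatomical
tissues; the two non-organ meridians have no tissue analogue, which is
why only ten of twelve meridians participate.

## 6. The synthetic-data generator

The generator (`sim_config()` plus `generate_*`) defines the study
conditions every test runs under. It emulates, with planted structure:

- **Herb tables**: uniform sampling within the four vocabularies (1 Qi,
  1–2 Flavors, 1–3 Meridians, 0–3 syndromes) — the simplest
  exchangeable null, since real property distributions are not
  recoverable.
- **Prescriptions**: each prescription seeds from a uniformly chosen
  herb and fills up with herbs sampled with log-linear preference
  (strength 6 by default) for sharing theory properties with the seed.
  This homophily is deliberate: real formulas are assembled from herbs
  with compatible theory roles, and the premise of putting a graph
  model on the co-prescription graph is precisely that the graph is
  informative about herb function. A uniformly random corpus would
  make the graph adversarial — neighborhood aggregation can only
  dilute the feature signal, because softmax attention over
  `aᵀ[Wh_i‖Wh_j]` cannot distinguish the self-loop from neighbors.
  Prescriptions hold 4–6 herbs by default, which keeps the
  thresholded co-occurrence graph sparse enough to be informative.
  Optional `synergy_blocks` with `block_boost` plant co-prescribed
  blocks for the link-prediction fixtures.
- **Disease labels**: each disease plants a few properties; a herb is
  associated with probability `plogis(coupling·(2·overlap − 1))`. At
  `coupling = 0` this is exactly 1/2 (the null case); at strong
  coupling herbs carrying any planted property are almost surely
  associated and the rest almost surely not. The `2·overlap − 1`
  centering makes the planted signal decisive at `overlap ≥ 1` instead
  of leaving single-overlap herbs at a coin flip, which would put an
  irreducible noise floor under every model.
- **Interactome**: a connected scale-free (or Erdős–Rényi) graph; the
  signature set is a breadth-first cluster (perturbation is local,
  like a pathway response); genes within `perturb_hops` of the
  signature receive |log2FC| centred on `perturb_effect` with random
  sign, everything gets Gaussian noise. The default radius is **one
  hop**: in scale-free graphs of desk scale the two-hop ball around a
  30-gene cluster covers half or more of the network (hubs), which
  destroys the plant by construction; one hop keeps the perturbed
  region a small minority (~20% at the 1000-gene default). The
  designated principal herb draws its targets inside the perturbed
  region, other herbs uniformly.
- **Tissue expression**: Gamma-distributed baseline nTPM; a herb's
  signature genes gain `meridian_effect` in tissues mapped to its
  meridians; the DEG table is constructed so the signature genes are
  exactly the rows passing the stated thresholds.

One RNG substream per generator (fixed offsets from the master seed),
so regenerating one table never shifts another; all outputs are
byte-identical across runs at a given seed.

What the generator does **not** emulate: real vocabulary text, real
tissue names, dosage, longitudinal prescriptions, correlated property
structure (e.g. flavors co-varying with natures), or read-level
RNA-seq. Tests passing on these conditions demonstrate that the
implementations recover the structure they claim to recover; they do
not certify performance numbers on real database extracts, which is
also why published headline figures are not comparison targets here.

## 7. Problem sizes and numerical choices

The shipped analyses use sizes a laptop handles in minutes: 200 herbs /
2000 prescriptions for the herb–disease study (hidden width 32, 4
heads, up to 200 epochs, patience 30); 50 herbs in four planted blocks
of 10 for the combination study (channels 32-32-16, up to 100 epochs);
a 1000-gene interactome with 30 signature genes and 9 formula herbs ×
25 targets for the proximity study (50–100 replicates); 500 genes × 54
tissues with 1000 permutations for the alignment study. Early stopping
keeps best-validation parameters; Adam uses the standard
(0.9, 0.999, 1e-8) moments; logs in losses are clamped at 1e-12;
attention softmax subtracts the per-neighborhood maximum. Ranking ties
break by herb ID so all orderings are total and reproducible.

## 8. Known limitations

- The GAT and DGCNN are full-batch, single-threaded R implementations:
  correct and reproducible, but not intended for graphs beyond a few
  thousand nodes.
- SEAL subgraph extraction sees the full observed adjacency except the
  target edge; large-scale implementations additionally hide entire
  validation/test edge sets during extraction. At the shipped fixture
  sizes the held-out-edge recommendation test shows the model does not
  depend on that leakage path.
- The proximity module implements the top-5% flag rule only; it does
  not implement degree-preserving permutation null models for network
  proximity, which answer a different calibration question.
- Hyperparameter search is exposed as configuration rather than an
  automated grid; the defaults were chosen on the synthetic conditions
  described above.
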