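# herbnet

Graph neural networks and network proximity for interpreting multi-herb
formulas under traditional herbal theory.

Multi-herb formulas are annotated, in traditional practice, with
theory labels — thermal nature (Qi), taste (Flavor), organ-channel
affinity (Meridian) and syndrome indications — and those labels carry
real signal about what the herbs do at the molecular level. `herbnet`
implements a desk-scale, fully testable version of a computational
paradigm that exploits this:

1. **Theory features.** Herb annotations are one-hot encoded into a
   binary feature matrix `X ∈ {0,1}^{n×f}` over a category-prefixed
   property vocabulary.
2. **Co-prescription graph.** Herb pairs co-occurring in **more than
   five** prescriptions become edges of an adjacency matrix `A`
   (strictly `count > 5`; a count of exactly 5 is not an edge).
3. **Herb–disease prediction (GAT).** A two-layer multi-head graph
   attention network scores every herb against `c` disease categories
   (multi-label). Attention follows
   `α_ij = softmax_j LeakyReLU(aᵀ[Wh_i ‖ Wh_j])`, heads are
   concatenated after layer 1 and averaged at the output layer, and the
   model is trained with binary cross-entropy, Adam, and early stopping
   on validation loss. Evaluation: micro-averaged AP, macro-averaged
   ROC-AUC, label-ranking average precision (LRAP) and label-ranking
   loss (LRL), with logistic-regression, KNN and mean-aggregation GCN
   baselines.
4. **Herb–herb combination prediction (SEAL-style).** Each candidate
   pair is classified from its enclosing subgraph (target edge removed;
   Double-Radius structural node labels; pretrained random-walk
   embeddings; theory features) by a DGCNN: degree-normalized graph
   convolutions `H^{l+1}_v = σ(W^l Σ_{u∈N_v} H^l_u / √(d_v d_u))`,
   global sort pooling, 1-D convolution and a dense readout, trained
   with `L = −1/N Σ y_i log σ(x_i) + (1−y_i) log(1−σ(x_i))`.
5. **Perturbation-weighted PPI proximity.** PPI edge weights derive
   from the averaged |log2FC| of the incident genes under formula
   perturbation. `Distance(i,j)` is the weighted shortest path in that
   network; the distance matrix `C` (signature genes × ingredient
   targets, STITCH-style score > 700) is flagged at the top 5% smallest
   distances (`floor(0.05·m)` finite entries, exactly), and theory
   groups are compared by two-sided Fisher exact tests on flag counts
   and Welch t-tests on distances. This is the interpretability core:
   the herb whose targets sit closest to the perturbation signature is
   the formula's principal ("JUN") herb.
6. **Meridian–tissue alignment.** Signature genes (DEG filter, e.g.
   `|log2FC| ≥ 0.5`, `p ≤ 0.05`) are aggregated per tissue (nTPM
   values strictly above 1000 excluded), and each meridian's mapped
   tissues are scored by rank (top-10) and by a permutation test over
   random gene sets.

Because the databases such analyses are built on (herb property tables,
prescription corpora, association databases, STRING/STITCH extracts,
tissue expression atlases) are not redistributable as files, the package
ships a **synthetic-data generator** that emulates all of them with
planted, recoverable structure — theory-coupled disease labels,
block-structured co-prescription, a perturbed PPI neighborhood enriched
for one designated principal herb, and meridian-aligned tissue
expression — so the entire pipeline is testable end to end from a
single seed.

## Worked example

The end-to-end pipeline on the default planted conditions:

```r
library(herbnet)
report <- run_all(seed = 1)
```

prints (abridged from the returned report):

```
GAT test metrics: AP = 0.799  ROC-AUC = 0.905  LRAP = 0.870  LRL = 0.112
SEAL test metrics: AP = 1.000  AUC = 1.000
principal herb: FH01   recovered by distance: TRUE   by Fisher test: TRUE
Fisher p (principal vs others): 7.6e-07 vs 8.5e-3 ... 0.86
planted meridian (meridian2): permutation p = 0.001, in top-10 tissues
```

The GAT recovers the planted property→disease coupling well above
chance; the SEAL model perfectly separates within-block from cross-block
pairs; the proximity module identifies the planted principal herb as the
one whose targets are nearest the perturbation signature (smallest mean
distance, most significant Fisher enrichment); and the tissue module
flags exactly the meridian that the generator elevated. Step-by-step use
of the individual modules is shown in the vignette
(`vignettes/herbnet-methods.Rmd`).

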