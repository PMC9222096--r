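# calcgraph

Graph-based classification of mammographic calcification distribution
patterns, with built-in interpretability and a synthetic phantom generator.

## What it does

The spatial arrangement of microcalcifications across a breast — the
BI-RADS distribution descriptors **diffuse**, **regional**, **grouped**,
**linear** and **segmental** — is strongly associated with malignancy risk,
and it is a *relational* property: twenty tiny spots are a cluster, a line
or a scatter only by virtue of their mutual geometry. calcgraph implements
an end-to-end pipeline that treats it that way:

1. **Detect** calcification candidates inside an Otsu-segmented breast mask
   with the white top-hat transform
   `I_T = I − (I ⊖ SE) ⊕ SE`, thresholded at a noise-scaled level
   (median + 5·MAD of the within-mask response; fixed and percentile rules
   are also available); an optional patch-verifier CNN (binary
   cross-entropy on 14×14 patches) filters false positives.
2. **Build a calcification graph** per image: nodes are detections carrying
   deep patch features fused with a learnable spatial embedding
   `X_emb = S·W_emb + b_emb`; edges are the symmetrised k-nearest-neighbour
   graph (k = 8) with geometric labels `(Δx, Δy, d)`.
3. **Classify** the graph with three edge-conditioned convolution layers

   `X_l(i) = (1/|N(i)|) Σ_{j∈N(i)} F_l(L_{j,i}; w_l) X_{l−1}(j) + b_l`,

   where a small filter network `F_l` generates each edge's filter matrix
   from its geometric label, followed by a readout and a two-layer sigmoid
   head. Training minimises the focal loss
   `L(p_t) = −(1 − p_t)^γ log p_t` (γ = 2), which down-weights easy
   majority-class examples — essential because grouped patterns are ~50% of
   cases while linear patterns are ~2%.
4. **Explain** each prediction with gradient-based per-node saliency
   (a graph adaptation of class-activation mapping) rendered as
   blue→yellow→red overlays.

Because clinical datasets with per-calcification annotations are scarce,
the package includes a phantom generator producing breast-shaped images (or
bare point patterns) with exact ground truth for every descriptor geometry,
used by the test-suite and the reproduction script.

## Worked example

```r
library(calcgraph)

# a grouped-pattern phantom with known spot positions
ph <- generate_phantom(pattern_spec("grouped", seed = 42))
mask <- segment_breast(ph$image)
cands <- detect_calcifications(ph$image, mask = mask)
length(cands)                         # 24 candidates from 24 planted spots
g <- build_graph(cands, ph$image, extractor = NULL, k = 8, label = "grouped")
print(g)
#> <calcification_graph> phantom-grouped-42: 24 nodes, 230 directed edges,
#>   9 features, label = grouped

# train and cross-validate on a 500-graph imbalanced benchmark
graphs <- unlist(lapply(0:4, function(s)
  generate_graph_dataset(class_mix("clinical"), 100, seed = s)$graphs),
  recursive = FALSE)
report <- cross_validate(graphs, gnn_config(),
                         benchmark_train_config(seed = 0),
                         n_folds = 5, seed = 0)
print(report)
#> accuracy: 0.998 (micro recall 0.998)
#> macro: precision 0.997  recall 0.999  specificity 1.000  F1 0.998  AUC 1.000
plot_outputs(report, "figs")          # confusion matrix + one-vs-rest ROCs
```

The report prints pooled 5-fold cross-validated metrics: overall accuracy,
macro/micro averages, and the per-class precision / recall / specificity /
F1 / AUC table (numbers above from one run of the example; the per-class
table shows which descriptors are confused with which).

A thin command-line wrapper over the same functions is provided at
`inst/cli/calcgraph.R` (`segment`, `detect`, `simulate`, `train`,
`predict`, `cv`, `explain`).

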