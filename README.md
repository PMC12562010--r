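# pathograph

Disease-specific pathogenicity prediction for genetic variants, cast as
link prediction on a heterogeneous biomedical knowledge graph.

Most missense variants seen in clinical sequencing end up as variants of
uncertain significance. Instead of scoring a variant in isolation,
`pathograph` asks the disease-specific question: *is this variant
pathogenic for this particular disease?* Formally, for a variant node $v$
and disease node $d$ in a typed knowledge graph (genes, proteins,
variants, diseases, pathways, phenotypes, drugs, GO terms, anatomy,
exposures), the model predicts the probability of a Disease–Variant edge:

$$\hat p(v, d) = \sigma\!\big(f_\theta([z_v; z_d])\big), \qquad
  z = \mathrm{ReLU}\big(\hat A\,\mathrm{ReLU}(\hat A X W_0)\,W_1\big),$$

a two-layer graph convolutional encoder (hidden widths 256 and 64,
$\hat A = \tilde D^{-1/2}(A+I)\tilde D^{-1/2}$ over the masked adjacency)
followed by a three-layer feed-forward decoder (hidden 64 and 32, sigmoid
output) on the concatenated pair embedding. Disease–Variant edges are
masked out of every adjacency used in training — they are the labels — and
training pairs are built by pairing pathogenic variants with their
diseases (label 1) and benign variants with their gene's diseases
(label 0). Two no-graph baselines (raw-embedding pair network, variant-only
network) quantify what the graph adds.

The package is self-contained at desk scale: it ships the graph store and
augmentation rules (protein-node splitting, variant attachment,
transient/permanent PPI typing from time-course co-expression, tissue
co-expression binning, edge masking), deterministic genomic context-window
extraction for SNVs/insertions/deletions/indels, pluggable node-embedding
providers with a deterministic hashing embedder, ClinVar-style filtering,
three split strategies (random 70/15/15, per-gene class-balanced,
date-based), evaluation statistics (balanced accuracy, Wilson score CI,
exact binomial test, bootstrap), and seeded synthetic-data generators with
a tunable planted signal — so the full pipeline runs and is tested without
any external database or pretrained model.

## Worked example

Simulate a dataset with a planted relational signal, fit the graph model,
and evaluate on held-out pairs:

```r
library(pathograph)

cfg   <- synth_config(n_genes = 15, seed = 55)     # toy genome + KG + variants
ds    <- simulate_dataset(cfg)
split <- random_split(ds$pairs, seed = 55)

fit <- patho_fit(ds$graph, ds$features, split, model = "gcn",
                 control = patho_validation_control(seed = 55))
fit
#> Disease-specific pathogenicity model (gcn)
#>   trained epochs: 300  selected epoch: 295  (validation BCE  0.002343 )
#>   pairs: train 617 / val 131 / test 131

evaluate(fit)
#> Variant-disease pair evaluation (n = 131 )
#>   confusion: TP 45  FP 0  TN 86  FN 0
#>   balanced accuracy:1 (95% Wilson CI 0.972-1)
#>   sensitivity: 1  specificity: 1  PPV: 1  NPV: 1
#>   binomial p-value (vs 0.5): 3.67e-40
```

The printed report gives the confusion matrix at the 0.5 threshold, the
balanced accuracy with its 95% Wilson interval on the adjusted success
count, and the exact binomial p-value against chance. At this toy size
(15 genes, planted signal strength 0.9) the model separates the held-out
pairs perfectly; `plot(fit)` draws the train/validation loss curves,
`predict(fit, pairs)` scores new pairs, `coef(fit)` returns the parameter
matrices, and `patho_fit(..., model = "baseline_pair")` fits the no-graph
baseline for comparison. `patho_control()` carries the published training
constants; `patho_validation_control()` is the desk-scale validation
configuration documented in the methods vignette.

A command-line wrapper over the same functions lives at
`inst/cli/pathograph.R` (`simulate`, `build-graph`, `extract-context`,
`embed`, `train`, `evaluate`, `run-all`), writing a `manifest.json` per
run for reproducibility.

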