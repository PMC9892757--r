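# mdagcan

Predicting microbe–disease associations with a graph convolutional
attention network.

Imbalances of the human microbiota are implicated in many diseases, but
experimentally mapping which microbe affects which disease is slow and
expensive. `mdagcan` addresses this as a bipartite link-prediction
problem: given a sparse binary matrix **A** ∈ {0,1}^(nd×nm) of known
disease–microbe associations (rows = diseases, columns = microbes), it
scores every unknown pair and ranks candidate microbes for a query
disease.

## The model

**Similarities.** Each disease and microbe gets a Gaussian interaction
profile (GIP) kernel similarity computed from its association profile,

    KM(mi, mj) = exp(−λ · ‖GIP(mi) − GIP(mj)‖²),
    λ = λ′ / mean_t ‖GIP(mt)‖²,

and, where gene/protein annotations are available, a functional
similarity from the best-match average (BMA) of normalized gene–gene
association scores:

    FD(a, b) = ( Σ_x max_y s(g_x, g_y) + Σ_y max_x s(g_x, g_y) ) / (m + n).

The two are fused conditionally: where functional evidence is absent the
GIP value is kept, otherwise `μ·GIP + (1−μ)·functional`.

**Heterogeneous graph.** The fused similarity blocks are symmetrically
degree-normalized and assembled with the association matrix into

    G_HN = [ β·DS*  A  ;  Aᵀ  β·MS* ],    H⁽⁰⁾ = [ 0  A ; Aᵀ  0 ],

where β controls the contribution of the similarity blocks.

**Encoder–decoder.** Node embeddings are learned with stacked graph
convolutional layers `H⁽ˡ⁺¹⁾ = tanh(D^(−1/2) G_HN D^(−1/2) H⁽ˡ⁾ W⁽ˡ⁾)`
followed by a graph attention layer that re-aggregates each node as the
softmax-attention-weighted average of its neighbors. A bilinear decoder
reconstructs the score matrix `Â = sigmoid(Z_d W′ Z_mᵀ)`, and all
parameters are trained with Adam to minimize a focal loss

    ψ = −α (1 − Â)^γ log Â   (positives),
    ψ = −α Â^γ log(1 − Â)    (negatives),

which down-weights easy samples to cope with the extreme class imbalance
of association matrices. Training, node/regular dropout, and Xavier
initialization are fully seeded and reproducible.

All four standard evaluation protocols are included: leave-one-out CV,
k-fold CV over known positives, and the cold-start "horizontal"
(disease-row) and "vertical" (microbe-column) holdout tests — each of
which recomputes the GIP similarities and the graph from the masked
training matrix only, so held-out labels can never leak into training.
A seeded synthetic-data generator with planted low-rank cluster
structure makes the whole pipeline runnable and testable without any
external database.

## Worked example

```r
library(mdagcan)

# synthetic benchmark: 30 diseases x 60 microbes, rank-3 planted structure
ds <- generate_dataset(synthetic_spec(seed = 1))
fd <- functional_similarity(ds$disease_annotations$map,
                            ds$disease_annotations$net, rownames(ds$A))
fm <- functional_similarity(ds$microbe_annotations$map,
                            ds$microbe_annotations$net, colnames(ds$A))

cfg <- mdagcan_benchmark_config(seed = 1)
fit <- mdagcan(ds$A, cfg, disease_functional = fd, microbe_functional = fm)
fit
#> Graph convolutional attention model for microbe-disease association
#>   30 diseases x 60 microbes, 177 known associations
#>   k = 64, 2 GCN + 1 GAT layer(s), 600 epochs
#>   focal loss: 6.34972 (epoch 1) -> 1.82152 (final)

summary(fit)
#> mdagcan fit: 30 diseases x 60 microbes, 177 positives
#>   training-set AUC        0.9096
#>   mean score, positives   0.5192
#>   mean score, negatives   0.3461
#>   final focal loss        1.82152

rank_candidates(fit, "disease_3", top_k = 5)
#>   rank microbe_id     score
#> 1    1 microbe_16 0.6109044
#> 2    2  microbe_8 0.4464322
#> 3    3 microbe_26 0.4394513
#> 4    4 microbe_38 0.4140758
#> 5    5 microbe_15 0.4130094

kfold_cv(ds$A, cfg, k = 5, seed = 1,
         disease_functional = fd, microbe_functional = fm)
#> kfold evaluation (5 fold(s), threshold 0.50)
#>   auc          0.8068 +/- 0.0805
#>   f1           0.2374 +/- 0.0924
#>   accuracy     0.9759 +/- 0.0038
#>   sensitivity  0.1917 +/- 0.1155
#>   specificity  0.9930 +/- 0.0061
```

The fit summary shows the model separating known positives (mean score
0.52) from unknown pairs (0.35) with a training-set AUC of 0.91; the
5-fold cross-validation — in which each fold's positives are masked,
similarities and the graph rebuilt, and the model retrained — estimates
how well genuinely unknown associations are recovered (AUC ≈ 0.81 on
this seed). `rank_candidates()` excludes a disease's known microbes and
ranks the rest by score, the package's end-use output.

A command-line interface over the same functions is installed as
`exec/mdagcan` with subcommands `simulate`, `similarity`, `train`, `cv`
and `predict`; run it with `--help` for usage.

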