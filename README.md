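# dginet

Topology-only prediction of multi-class drug–gene interactions on bipartite
graphs.

## The problem

Drug–gene interactions (a drug upregulating a gene, inhibiting its product,
binding it, …) underpin drug mechanism, adverse-effect prediction, and
repurposing. Most predictors rely on chemical or genomic features, which are
missing precisely for the novel compounds and poorly annotated genes where
prediction matters most. `dginet` instead classifies the relation type of a
drug–gene pair from **network topology alone**: every node's only "features"
are learnable embedding vectors, trained end to end on the labelled
interaction graph.

For whom: computational biologists and cheminformaticians who have a
labelled bipartite interaction network (edge list of
`drug_id, gene_id, label`) and want typed predictions for unobserved pairs
among the same drugs and genes (the setting is transductive).

## The model

Given drugs $V_d$ and genes $V_g$ with labelled edges
$E \subseteq V_d \times V_g \times \{1..C\}$, the unified adjacency
$A_\text{full} = \begin{bmatrix} 0 & R \\ R^\top & 0\end{bmatrix}$ is
self-looped and symmetrically normalized,
$\hat A = D^{-1/2}(A_\text{full} + I)D^{-1/2}$. Two encoders run in
parallel from a shared embedding table:

* a **lightweight graph attention** branch — shared projection $z_i = W h_i$,
  neighborhood softmax over
  $e_{ij} = \mathrm{LeakyReLU}(a^\top[z_i \| z_j])$, output
  $h_i' = \mathrm{L2Norm}(\mathrm{ELU}(\sum_j \alpha_{ij} z_j))$;
* a **gated hyperedge convolution** branch — each interaction is a
  two-node hyperedge; node MLP → hyperedge mean → hyperedge MLP →
  degree-normalized aggregation $z_i'$ → sigmoid gate
  $g_i = \sigma(W_g[h_i \| z_i'] + b_g)$ → fusion
  $h_i \leftarrow g_i \odot z_i' + (1-g_i)\odot h_i$.

The two views feed a **multi-positive temperature-scaled contrastive loss**
(cross-view vectors of the same node are mutual positives),

$$\mathcal{L}_{cl} = -\tfrac{1}{|N|}\textstyle\sum_i \log
\frac{\sum_{j\in P(i)} e^{\mathrm{sim}(i,j)/\tau}}
     {\sum_{k\neq i} e^{\mathrm{sim}(i,k)/\tau}},$$

and their sum scores pairs through a small perceptron head with softmax.
The total objective
$\mathcal{L} = \alpha\mathcal{L}_{reg} + \beta\mathcal{L}_{cl} +
\gamma\mathcal{L}_{ce}$ is optimized full-batch with AdamW under a
triangular cyclic learning rate. Seed-varied members are ensembled by
majority vote. Splits are transductive (every evaluated node retains a
training edge), and non-edges for negative sampling are drawn
frequency-smoothed, $p(\text{node}) \propto (\text{degree}+1)^{-0.75}$.

See `vignettes/topology-dgi.Rmd` for assumptions, parameter meanings,
numerical choices, and limitations.

## Worked example

Simulate a heavy-tailed interaction network with planted relation structure
(50 drugs, 200 genes, 2,000 edges, 2 relation classes determined by latent
node blocks, 5% label noise), split it transductively, train, evaluate:

```r
library(dginet)

syn   <- simulate_dgi_network(synth_config(seed = 0))
split <- transductive_split(syn$graph, seed = 0)
split
#> <dgi_split> 1440 train / 160 val / 400 test edges (72.0% / 8.0% / 20.0%)

fit <- dgi_train(syn$graph, split, dgi_config(seed = 0))
fit
#> <dgi_fit> F=64, 2 layer(s), sum aggregation; 200 epochs; best val acc 0.9375 (epoch 95)

evaluate_fit(fit, syn$graph, split$test)
#> <dgi_metrics> n=400  acc 0.9050 | macro-F1 0.9048 | AUROC 0.9235 | AUPR 0.9125 | MCC 0.8113
```

Held-out accuracy of 0.905 against a 0.5 chance level means the model
recovered the planted block structure almost up to the 5% label-noise
ceiling (~0.95): the embeddings learned each node's latent block purely
from labelled topology. `tidy(fit)` returns the per-epoch history,
`autoplot(fit)` plots it, and `predict(fit, pairs)` scores new pairs —
refusing, by design, any drug or gene absent from the training graph.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/dginet.R simulate --seed 3 --out runs/sim
Rscript inst/cli/dginet.R split    --edges runs/sim/edges.tsv --seed 1 --out runs/splits
Rscript inst/cli/dginet.R train    --edges runs/sim/edges.tsv --splits runs/splits --seed 0 --out runs/fit
Rscript inst/cli/dginet.R evaluate --edges runs/sim/edges.tsv --splits runs/splits \
        --checkpoint runs/fit/checkpoint.rds --out runs/eval
```

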