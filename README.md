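# cellConsensus

Ensemble consensus clustering of single cells by graph-regularized
Bernoulli factorization.

## What it is for

Single-cell RNA-seq clustering tools (SC3, CIDR, Seurat, t-SNE+k-means,
...) routinely disagree, and most need the number of clusters up front.
`cellConsensus` is for analysts who have already run several such tools on
the same cells and want one robust partition out of them: it fuses the
base label sets into a weighted consensus matrix, factorizes that matrix
under a probabilistic model that infers the cluster count itself, and uses
a nearest-neighbour graph built from the expression data to keep weak base
clusterings from dragging the result down. The base clusterers themselves
are never run by this package — it consumes their label files, or
surrogates from its own synthetic generator.

## The model

Each base partition \(p\) becomes a binary co-membership matrix \(B_p\);
partitions are weighted by their normalized Calinski–Harabasz scores
\(u_p\) in log1p(CPM) feature space, fused as \(W = \sum_p u_p B_p\), and
binarized at a strict-majority threshold \(W_t = 0.5\). With
\(s_{ij} = \sum_{z=1}^{Q} h_{iz} h_{jz}\), each consensus entry is
modelled as

\[ w_{ij} \sim \mathrm{Bernoulli}\!\left(1 - e^{-s_{ij}}\right),
   \qquad i < j, \]

where the nonnegative \(n \times Q\) matrix \(H\) holds each cell's
affinity to \(Q\) latent clusters. Automatic-relevance-determination
priors — Gaussian columns with scales \(\beta_z\) under an
inverse-Gamma\((a, b)\) hyperprior — drive unused columns to zero, so the
number of surviving columns is the inferred cluster count \(C\). A KNN
graph Laplacian penalty \(\alpha\,\mathrm{tr}(H^\top L H)\) ties factor
profiles of neighbouring cells together (\(\alpha = 0\) disables it and
yields the unregularized ablation model). \(H\) is fitted by damped
multiplicative updates, \(\beta\) by its closed form
\(\beta_z = (2b + \sum_i h_{iz}^2)/(n + 2a + 2)\), with multi-restart
optimization; labels are the row-wise argmax of the winning \(H^*\). The
methods vignette (`vignettes/consensus-model.Rmd`) derives and motivates
every piece.

## Worked example

```r
library(cellConsensus)

sim <- simulate_ensemble(simulation_scenario(seed = 7))  # 200 cells, 5 types,
                                                         # 4 noisy base methods
fit <- consensus_pgm(sim$expression, sim$partitions,
                     control = pgm_control(n_restarts = 5, seed = 7),
                     truth = sim$truth)
fit
#> Consensus clustering (graph-regularized Bernoulli factorization)
#>   cells: 200, base methods: 4, alpha = 100
#>   recovered clusters C = 5
#>   objective = -1873.655 (restart 5/5)
#>   vs truth: ARI = 1, NMI = 1

summary(fit)$weights
#>    method ch_score    weight
#>  method_1 78.50648 0.3264331
#>  method_2 57.73100 0.2400478
#>  method_3 48.83071 0.2030401
#>  method_4 55.42971 0.2304790
```

The four base partitions carry label noise of 5–20%; the cleanest method
earns the largest Calinski–Harabasz weight, the ARD prior prunes the
25-column model down to exactly the 5 planted types, and the recovered
labels match the ground truth (ARI = NMI = 1). `coef(fit)` returns
\(H^*\), `fitted(fit)` the labels, `plot(fit)` the objective trace, and
`parameter_sweep()` grid-searches \((b, \alpha)\) against a reference
partition.

A thin command-line driver ships in `exec/cellconsensus` with subcommands
`simulate`, `run`, `evaluate` and `sweep`; run it with `Rscript` against
expression and label files (see `--help`-style usage at the top of the
script).

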