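# hexsom

Self-organising maps on a supra-hexagonal lattice for tabular omics
matrices.

## The problem

Downstream omics data — expression, replication timing, methylation — almost
always arrive as a genes × samples matrix with many genes (large *p*) and few
samples (small *n*). A first look at such a matrix needs the gene dimension
compressed (clustering) and projected onto something a person can read (a 2D
map). `hexsom` does both at once with a self-organising map (SOM) whose
output lattice is a *supra-hexagon*: a bounded disc of smaller hexagons
arranged in concentric circles around a centre node. Because omics data are
typically normalised so that most genes sit near zero and only coherent
changes stand out, a radially symmetric lattice is a natural canvas: the
unchanging bulk gravitates together and non-random structure forms visible
territories.

The package is aimed at bioinformaticians and bench scientists who want a
sanity check and a quick, reproducible exploration of any numeric
genes × samples table — from the R prompt or from a shell.

## The method

A radius-*r* supra-hexagonal map has

```
M(r) = 1 + 3 r (r − 1)
```

nodes (circle *k* ≥ 2 contributes 6(*k* − 1) nodes; radius 8 gives 169).
Nodes are indexed from the centre outward, anti-clockwise within each
circle. Each node *j* carries a prototype vector **m**ⱼ in input space; the
prototypes jointly form the *codebook matrix*. Training follows the Kohonen
learning rule. In batch form, each epoch replaces every prototype by a
neighbourhood-weighted mean of the data:

```
m_j ← Σᵢ k(‖c(b(xᵢ)) − c(j)‖, σ(t)) · xᵢ  /  Σᵢ k(·)
```

where b(**x**ᵢ) is the best-matching unit (BMU) of row *i*, c(·) the node's
2D position, and k one of four neighbourhood kernels (gaussian, bubble,
cut-gaussian, epanechnikov) with a width σ(*t*) that shrinks over a
two-phase schedule. On top of the trained map the package computes:

* **U-matrix and hit histogram** — per-node mean prototype distance to map
  neighbours, and per-node counts of best-hitting genes;
* **meta-clustering** — U-matrix local minima become seeds, and a greedy
  region-growing pass guarantees each meta-cluster is contiguous on the map;
* **sample landscape** — samples laid out on a small square lattice (trained
  on sample vectors or on a pairwise similarity matrix: Pearson, Spearman,
  Kendall tau-b, Euclidean, cityblock, cosine, or mutual information) so
  that geometric proximity reflects profile similarity;
* **overlay** — any extra per-gene data layer projected onto the map by
  kernel-weighted accumulation normalised by kernel-weighted hits, so a
  0/1 layer becomes a per-node probability.

## Worked example

```r
library(hexsom)

sim <- simulate_genes(n_genes = 600, n_samples = 6, clusters = 4,
                      background_fraction = 0.3, tau = 3, sigma_n = 0.3,
                      seed = 7)
fit <- som_train(sim$matrix, config = som_config(seed = 7))
fit$codebook$spec$n          # 127 nodes (auto radius 7 for 600 genes)
tail(fit$qe_trace, 1)        # final quantization error 0.5478

seeds <- find_seeds(umatrix(fit$codebook))
seeds                        # 1  92  98 104 116 122
mc <- partition_grow(fit$codebook, seeds)
table(planted = sim$labels, meta = gene_clusters(fit$mapping, mc))
```

```
       meta
planted   1   2   3   4   5   6
      0 133   0   0   0   0  47
      1   0   0   0 105   0   0
      2   0 105   0   0   0   0
      3   0   0   0   0 105   0
      4   0   0 105   0   0   0
```

Six U-matrix minima seed six contiguous meta-clusters: each of the four
planted clusters is recovered intact (105/105 genes), and the 180 background
genes split between the central cluster 1 and its neighbour 6 — exactly the
"most genes do not change" bulk the radial design puts at the centre.
`train_landscape(fit$codebook, seed = 7)` then arranges the six samples on a
3 × 2 lattice, and overlaying a 0/1 layer that tracks planted cluster 1
(`overlay_data`) yields per-node probabilities ranging from 0.04 on the
far side of the map to 0.89 on that cluster's territory.

The same pipeline runs from a shell:

```sh
Rscript exec/hexsom simulate --out sim --genes 600 --seed 7
Rscript exec/hexsom train --input sim_matrix.tsv --out res --seed 7
Rscript exec/hexsom partition --prefix res
Rscript exec/hexsom landscape --prefix res --metric pearson --seed 7
Rscript exec/hexsom overlay --prefix res --data sim_overlay_data.tsv
Rscript exec/hexsom plot --prefix res --what umatrix --out umatrix.svg
```

Every subcommand is byte-reproducible under `--seed` and echoes its
effective configuration to a JSON sidecar next to its outputs.

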