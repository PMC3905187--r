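---
title: "Supra-hexagonal self-organising maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supra-hexagonal self-organising maps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexsom)
```

## The lattice

The output space is a bounded hexagonal disc: a centre node surrounded by
concentric circles of hexagons, circle $k \ge 2$ holding $6(k-1)$ nodes, so
a radius-$r$ map has $1 + 3r(r-1)$ nodes. Internally each node carries
axial coordinates $(q, r)$ with hex distance
$(|q| + |r| + |q+r|)/2$, embedded in the plane as
$x = q + r/2,\; y = r\sqrt{3}/2$, which places adjacent hexagons at
Cartesian distance exactly 1. The map is a disc, not a torus: there is no
wrap-around, outer nodes have 3 or 4 neighbours and interior nodes 6.

Node numbering starts at the centre and proceeds circle by circle outward,
anti-clockwise within each circle. Where exactly a circle's numbering
*starts* is a free convention; we fix it at the cell on the positive $x$
axis (axial $(k-1, 0)$ for circle $k$). Any fixed start preserves all map
semantics — distances, adjacency, training — so the choice is purely about
having one deterministic, documented labelling.

## Training

Batch learning (the default) updates every prototype once per epoch as a
neighbourhood-weighted mean of all input rows; sequential learning presents
rows one at a time in a seeded random order and moves prototypes by
$\alpha\, k(d, \sigma)\,(x - m)$. Four kernels are available (gaussian,
bubble, cut-gaussian, epanechnikov); gaussian is the default because it is
smooth and support-free, so no node can starve. BMU search uses Euclidean
distance in input space only; other similarity metrics belong to the sample
landscape, where they describe samples rather than genes.

Tunable parameters and defaults:

* **radius** — auto-sized as the smallest $r$ with node count
  $\ge 5\sqrt{G}$ (capped at 15), the usual SOM sizing heuristic of roughly
  a handful of genes per node.
* **schedule** — two phases: rough ordering (10 epochs,
  $\sigma: \max(r/2, 1) \to \max(r/8, 1)$, $\alpha: 0.5 \to 0.05$) then
  fine tuning (40 epochs, $\sigma \to 1$, $\alpha: 0.05 \to 0.01$), with
  $\sigma$ and $\alpha$ interpolated linearly within each phase. The fine
  phase deliberately **ends at $\sigma = 1$**, the classical convention for
  batch SOMs: if $\sigma$ keeps shrinking towards zero the neighbourhood
  kernel degenerates into a delta and the update becomes plain k-means over
  127-odd centroids — quantization error keeps dropping, but topological
  ordering between neighbouring prototypes is destroyed, the U-matrix turns
  wrinkled, and local-minima seeding fragments genuine clusters into
  multiple meta-clusters. A terminal neighbourhood of one lattice step keeps
  adjacent prototypes coupled, which is exactly what the U-matrix and the
  partitioning stage rely on.
* **initialisation** — linear by default: prototypes are laid on the plane
  of the first two principal directions of the column-centred data, node
  coordinates rescaled to the data's extent along each direction (with a
  canonical sign fix so results do not depend on input row order); data of
  rank < 2 fall back to seeded uniform initialisation within per-component
  ranges.

Ties in BMU search are detected at an absolute tolerance of $10^{-12}$ on
the distance, the winner is the lowest-index tie, and the full tie set is
retained because the overlay stage splits a gene's weight equally across
its co-best nodes. Nodes receiving zero total kernel weight in a batch
epoch (possible with compact-support kernels) keep their previous prototype
and trigger a warning.

## Node statistics and partitioning

The U-matrix value of a node is the mean input-space distance between its
prototype and its map neighbours; low values mark cluster interiors. Seeds
for meta-clustering are the local minima of this field, with a plateau rule
for exact ties: a connected set of equal-valued weak minima counts once,
represented by its lowest index — so a constant field yields exactly one
seed rather than one per node. Since the global minimum always qualifies,
at least one seed always exists.

Two partitioning modes share those seeds. Nearest-seed labelling assigns
every node to the seed with the closest prototype; it is simple but can
produce clusters that are disconnected on the map. Region growing
guarantees contiguity: clusters start at their seeds and repeatedly claim
the unassigned frontier node whose prototype is closest to a claiming
cluster's *seed* prototype (ties: lower node index, then lower cluster id).
Growing towards the seed prototype rather than a running cluster mean keeps
the procedure deterministic and independent of assignment order; its
output provably induces connected subgraphs, which the tests verify by
breadth-first search on every run.

## The sample landscape

Samples are re-described as feature vectors — either columns of the input
or of the codebook, or rows of a pairwise similarity matrix, which makes
the layout cost independent of the number of genes. Supported metrics:
Pearson, Spearman (Pearson on average ranks), Kendall tau-b, Euclidean,
cityblock, cosine, and mutual information. Mutual information uses a
plug-in estimator on $\lceil\sqrt{F}\rceil$ equal-width bins per variable
over each variable's observed range, reported in bits, with the diagonal
equal to the discretised entropy; this is the simplest defensible
estimator for the short vectors involved, and its bias is irrelevant here
because only the *ordering* of similarities shapes the layout. When a
correlation-type metric must act as a distance internally we use
$d = 1 - s$. Zero-variance vectors under correlation metrics yield 0 with
a warning rather than `NA`, so one flat sample cannot poison the layout.

The layout itself is a small sheet-topology SOM on an
$\lceil\sqrt{S}\rceil \times \lceil S/n_x \rceil$ 8-connected square
lattice, trained with the same schedules. Each sample lands on its
best-matching cell; collisions are resolved deterministically by placing
samples in order of decreasing best-matching margin (the confident ones
first) and moving a colliding sample to the nearest free cell (Euclidean,
ties row-major). Display order for per-sample component maps is row-major
over cells, ties by sample id.

## Overlay

An additional per-gene layer $y$ is projected onto the map by computing,
per node $j$, kernel-weighted hits $h_j = \sum_i w_{ij}$ and accumulated
values $A_j = \sum_i w_{ij} y_i$, and reporting $O_j = A_j / h_j$. The
weights $w_{ij}$ spread each gene over the neighbourhood of its BMU (ties
split equally), which avoids the brittleness of assigning a gene rigidly to
a single node. The normalisation makes the operation exact on constants —
overlaying a constant column returns that constant at every defined node
for every kernel and width — and linear in the overlaid columns; both are
tested directly, and with a point kernel (bubble, $\sigma = 0.5$) the
overlay reduces to plain per-node means, which the tests check against a
brute-force oracle. The default overlay kernel is gaussian with
$\sigma = 1$, matching the terminal training neighbourhood. Nodes with
weighted hits below $\varepsilon = 10^{-9}$ are reported as undefined and
only imputed (iterated means of defined neighbours) when the overlay is
repackaged as an artificial codebook for landscape training.

## Synthetic data

The generator emulates the structure the method assumes: a background
fraction (default 0.3) of genes that are pure noise around zero — the
"most genes do not change" bulk — plus clusters whose centroids are drawn
once from $\mathcal{N}(0, \tau^2)$ per component and whose genes add
$\mathcal{N}(0, \sigma_n^2)$ noise. Gaussian families are used throughout
for tractability. The default study condition used by the recovery tests is
600 genes × 6 samples, 4 clusters, $\tau = 3$, $\sigma_n = 0.3$ — cleanly
separable, desk-scale, and small enough that the full
simulate–train–partition pipeline runs in seconds. What the generator does
**not** emulate: heavy-tailed noise, gene–gene correlation within a
cluster beyond the shared centroid, sample-specific scale effects, and
missing values. Passing the recovery tests therefore demonstrates that the
machinery is correct on data satisfying its own assumptions, not that any
particular real dataset will partition as cleanly.

Overlay layers are generated to track designated clusters: logical layers
flip a biased coin ($p_{in}$ inside, $p_{out}$ outside), numeric layers add
a mean shift, mirroring promoter-class indicators and expression levels
respectively.

## Numerical and serialisation choices

* BMU tie tolerance $10^{-12}$ absolute; similarity-matrix symmetry
  asserted at $10^{-9}$.
* TSV output serialises numbers with 15 significant digits, enough to
  round-trip at $10^{-12}$ absolute for values of order 1.
* SVG rendering writes polygon primitives directly with fixed 4-decimal
  coordinates, so identical input yields byte-identical documents; colour
  scales are linear, diverging and anchored at zero when the field spans
  both signs, sequential otherwise.
* All randomised steps (uniform initialisation, sequential presentation
  order, the generator) take explicit seeds; the command-line pipeline is
  byte-reproducible end to end under `--seed`.

## Limitations

* One topology family per use: the gene map is always the hexagonal disc,
  the sample landscape always a small sheet; cylinders and toroids are out
  of scope.
* Sequential training is a plain R loop — fine at desk scale, slow for very
  large matrices; batch training is vectorised and is the default.
* Nearest-seed partitions may be discontiguous by construction; use region
  growing when contiguity matters.
* The map gives a *view*, not a test: meta-cluster boundaries carry no
  significance statement.
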