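Package: hexsom
Title: Self-Organising Maps on a Supra-Hexagonal Lattice for Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains a self-organising map with a radially symmetric
    supra-hexagonal topology (a bounded disc of hexagons arranged in
    concentric circles) on a genes-by-samples numeric matrix, producing a
    codebook of per-node prototype vectors. Node-level diagnostics (U-matrix,
    hit histogram, prototype patterns), region-growing meta-clustering from
    local-minima seeds, a square-lattice sample landscape under configurable
    similarity metrics, and kernel-weighted overlay of additional per-gene
    data layers onto the trained map are built on top of the trained map.
    Includes a synthetic-data generator with planted gene clusters, TSV
    import/export, SVG map rendering, and a command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
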