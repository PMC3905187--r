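# Meta-clustering of a trained map: local-minima seeds, nearest-seed
# labelling, and contiguity-guaranteeing region growing.

#' Seed nodes from the local minima of a node field
#'
#' A node is a seed iff its value is less than or equal to all adjacent
#' values and it is the lowest-index member of its equal-value plateau (the
#' connected set of equal-valued nodes that jointly satisfy the condition).
#' The global minimum always qualifies, so at least one seed is returned.
#' The usual field is the [umatrix()], whose minima mark cluster interiors.
#'
#' @param field A [node_field()].
#' @return Integer vector of seed node indices, sorted.
#' @export
find_seeds <- function(field) {
  spec <- field$spec
  v <- field$values
  weak <- vapply(seq_len(spec$n), function(j) {
    nb <- spec$adjacency[[j]]
    length(nb) == 0L || all(v[j] <= v[nb])
  }, logical(1))
  cand <- which(weak)
  # connected components of candidates linked through equal-valued neighbours
  seen <- logical(spec$n)
  seeds <- integer(0)
  for (s in cand) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(spec$adjacency[frontier]))
      nxt <- nxt[!seen[nxt] & nxt %in% cand & v[nxt] == v[s]]
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    seeds <- c(seeds, min(comp))
  }
  sort(seeds)
}

new_meta_clustering <- function(labels, seeds, method) {
  structure(list(labels = as.integer(labels), seeds = as.integer(seeds),
                 method = method),
            class = "meta_clustering")
}

#' Partition map nodes by nearest seed prototype
#'
#' Labels every node with the seed whose prototype is nearest in input-space
#' Euclidean distance (ties broken by the lower seed index). Clusters are not
#' guaranteed to be contiguous on the map; use [partition_grow()] for that.
#'
#' @param codebook A `som_codebook`.
#' @param seeds Integer vector of seed node indices.
#' @return A `meta_clustering`: list with per-node `labels` (cluster ids
#'   `1..K` in seed order), `seeds`, and `method`.
#' @export
partition_nearest <- function(codebook, seeds) {
  seeds <- check_node_index(seeds, codebook$spec)
  if (length(seeds) == 0L) stop("'seeds' must be non-empty", call. = FALSE)
  proto <- codebook$prototypes
  d2 <- cross_dist2(proto, proto[seeds, , drop = FALSE])
  labels <- max.col(-d2, ties.method = "first")
  new_meta_clustering(labels, seeds, "nearest")
}

#' Partition map nodes by greedy region growing from seeds
#'
#' Each cluster starts at its seed; repeatedly, over all pairs of an
#' unassigned node and a cluster it is map-adjacent to, the pair with the
#' smallest Euclidean input-space distance between the node's prototype and
#' the cluster's seed prototype is assigned (ties: lower node index, then
#' lower cluster id). Every resulting cluster is connected under the map
#' adjacency.
#'
#' @inheritParams partition_nearest
#' @return A `meta_clustering` with contiguous clusters.
#' @export
partition_grow <- function(codebook, seeds) {
  spec <- codebook$spec
  seeds <- check_node_index(seeds, spec)
  if (length(seeds) == 0L) stop("'seeds' must be non-empty", call. = FALSE)
  proto <- codebook$prototypes
  k <- length(seeds)
  # distance of every node's prototype to every seed prototype
  d2 <- cross_dist2(proto, proto[seeds, , drop = FALSE])
  labels <- rep(NA_integer_, spec$n)
  labels[seeds] <- seq_len(k)
  while (anyNA(labels)) {
    best <- c(Inf, NA_integer_, NA_integer_) # dist2, node, cluster
    for (u in which(is.na(labels))) {
      cl <- sort(unique(labels[spec$adjacency[[u]]]))
      cl <- cl[!is.na(cl)]
      for (c0 in cl) {
        if (d2[u, c0] < best[1] ||
            (d2[u, c0] == best[1] &&
             (u < best[2] || (u == best[2] && c0 < best[3])))) {
          best <- c(d2[u, c0], u, c0)
        }
      }
    }
    labels[best[2]] <- as.integer(best[3])
  }
  new_meta_clustering(labels, seeds, "grow")
}

#' Map per-gene meta-cluster labels through a mapping
#'
#' Convenience: each gene inherits the meta-cluster of its best-matching
#' node.
#'
#' @param mapping A `som_mapping`.
#' @param clustering A `meta_clustering` over the same map.
#' @return Named integer vector of per-gene cluster ids.
#' @export
gene_clusters <- function(mapping, clustering) {
  stats::setNames(clustering$labels[mapping$bmu], names(mapping$bmu))
}
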