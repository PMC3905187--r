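# Independent brute-force oracles, kept deliberately naive (loops, no shared
# code paths with the package internals).

hexdist_pair <- function(q1, r1, q2, r2) {
  (abs(q1 - q2) + abs(r1 - r2) + abs(q1 + r1 - q2 - r2)) / 2
}

# all axial cells within hex distance radius-1 of the origin
enumerate_hex_cells <- function(radius) {
  s <- radius - 1L
  out <- NULL
  for (q in -s:s) for (r in -s:s) {
    if (hexdist_pair(q, r, 0, 0) <= s) out <- rbind(out, c(q, r))
  }
  out
}

oracle_adjacency <- function(coords) {
  n <- nrow(coords)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i != j &&
          hexdist_pair(coords[i, 1], coords[i, 2],
                       coords[j, 1], coords[j, 2]) == 1) {
        nb <- c(nb, j)
      }
    }
    adj[[i]] <- nb
  }
  adj
}

oracle_bmu <- function(proto, v) {
  d <- numeric(nrow(proto))
  for (j in seq_len(nrow(proto))) d[j] <- sqrt(sum((proto[j, ] - v)^2))
  ties <- which(d - min(d) <= 1e-12)
  list(winner = ties[1], ties = ties)
}

oracle_umatrix <- function(proto, adjacency) {
  vapply(seq_len(nrow(proto)), function(j) {
    nb <- adjacency[[j]]
    if (length(nb) == 0) return(0)
    mean(vapply(nb, function(b) sqrt(sum((proto[j, ] - proto[b, ])^2)),
                numeric(1)))
  }, numeric(1))
}

oracle_hits <- function(x, proto) {
  hits <- integer(nrow(proto))
  for (i in seq_len(nrow(x))) {
    w <- oracle_bmu(proto, x[i, ])$winner
    hits[w] <- hits[w] + 1L
  }
  hits
}

oracle_nearest_seed <- function(proto, seeds) {
  labels <- integer(nrow(proto))
  for (u in seq_len(nrow(proto))) {
    d <- vapply(seeds, function(s) sqrt(sum((proto[u, ] - proto[s, ])^2)),
                numeric(1))
    labels[u] <- which.min(d) # which.min takes the first (lowest seed index)
  }
  labels
}

# plateau-merging local-minima scan via igraph components
oracle_local_minima <- function(values, adjacency) {
  n <- length(values)
  weak <- vapply(seq_len(n), function(j) {
    nb <- adjacency[[j]]
    length(nb) == 0 || all(values[j] <= values[nb])
  }, logical(1))
  cand <- which(weak)
  edges <- NULL
  for (i in cand) {
    for (j in adjacency[[i]]) {
      if (j > i && j %in% cand && values[i] == values[j]) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
        else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = cand))
  comp <- igraph::components(g)
  sort(vapply(seq_len(comp$no), function(k) {
    min(as.integer(names(comp$membership)[comp$membership == k]))
  }, integer(1)))
}

cluster_is_connected <- function(nodes, adjacency) {
  if (length(nodes) <= 1) return(TRUE)
  seen <- nodes[1]
  repeat {
    grow <- setdiff(intersect(unlist(adjacency[seen]), nodes), seen)
    if (length(grow) == 0) break
    seen <- c(seen, grow)
  }
  length(seen) == length(nodes)
}

# one Lloyd step of k-means with given centres
oracle_lloyd_step <- function(x, centres) {
  assign <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- vapply(seq_len(nrow(centres)),
                function(j) sum((x[i, ] - centres[j, ])^2), numeric(1))
    assign[i] <- which.min(d)
  }
  out <- centres
  for (j in unique(assign)) {
    out[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  out
}

# BFS graph distance from a source node (for constructing monotone fields)
graph_distance <- function(src, adjacency) {
  n <- length(adjacency)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  k <- 0
  while (length(frontier) > 0) {
    k <- k + 1
    nxt <- setdiff(unlist(adjacency[frontier]), which(is.finite(d)))
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

random_codebook <- function(spec, d = 3) {
  proto <- matrix(stats::rnorm(spec$n * d), spec$n, d)
  colnames(proto) <- paste0("s", seq_len(d))
  rownames(proto) <- seq_len(spec$n)
  structure(list(prototypes = proto, spec = spec,
                 col_ids = colnames(proto)),
            class = "som_codebook")
}

named_matrix <- function(data, nrow, ncol) {
  matrix(data, nrow, ncol,
         dimnames = list(paste0("g", seq_len(nrow)),
                         paste0("s", seq_len(ncol))))
}
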