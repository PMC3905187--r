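# Supra-hexagonal lattice: a bounded disc of hexagons in concentric circles
# around a centre node. Axial coordinates (q, r); no wrap-around.

#' Number of nodes in a supra-hexagonal map
#'
#' A map of radius `r` consists of `r` concentric circles of hexagons (the
#' centre node counts as circle 1); circle `k >= 2` holds `6 * (k - 1)` nodes,
#' giving `1 + 3 * r * (r - 1)` nodes in total.
#'
#' @param radius Positive integer; number of concentric circles.
#' @return Integer node count.
#' @examples
#' hex_node_count(8) # 169
#' @export
hex_node_count <- function(radius) {
  check_radius(radius)
  as.integer(1L + 3L * radius * (radius - 1L))
}

check_radius <- function(radius) {
  if (length(radius) != 1L || !is.numeric(radius) || is.na(radius) ||
      radius < 1 || radius != round(radius)) {
    stop("'radius' must be a single positive integer", call. = FALSE)
  }
  invisible(as.integer(radius))
}

# axial hex distance to the origin
hex_dist0 <- function(q, r) (abs(q) + abs(r) + abs(q + r)) / 2

#' Cartesian embedding of axial hex coordinates
#'
#' Pointy-top embedding: `x = q + r/2`, `y = r * sqrt(3)/2`. Adjacent
#' hexagons are at Cartesian distance exactly 1.
#'
#' @param q,r Integer axial coordinates (vectorised).
#' @return Two-column numeric matrix with columns `x`, `y`.
#' @export
hex_to_cartesian <- function(q, r) {
  cbind(x = q + r / 2, y = r * sqrt(3) / 2)
}

#' Build a supra-hexagonal map specification
#'
#' Nodes are indexed from 1 at the centre, then circle by circle outward.
#' Within each circle the first node sits on the positive x axis (axial
#' `(k - 1, 0)` for circle `k`) and subsequent nodes follow anti-clockwise.
#' Adjacency contains exactly the node pairs at hex distance 1.
#'
#' @param radius Positive integer; number of concentric circles.
#' @return An object of class `hexmap_spec` (and `map_spec`): a list with
#'   `radius`, `n` (node count), `coords` (n x 2 integer matrix of axial
#'   `q`, `r`), `xy` (n x 2 Cartesian embedding), `circle` (per-node circle
#'   number), and `adjacency` (list of integer neighbour indices per node).
#' @examples
#' spec <- hex_map(3)
#' spec$n # 19
#' @export
hex_map <- function(radius) {
  radius <- check_radius(radius)
  qs <- 0L
  rs <- 0L
  if (radius > 1L) {
    for (s in seq_len(radius - 1L)) {
      grid <- expand.grid(q = -s:s, r = -s:s)
      keep <- hex_dist0(grid$q, grid$r) == s
      rq <- grid$q[keep]
      rr <- grid$r[keep]
      xy <- hex_to_cartesian(rq, rr)
      ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
      ord <- order(ang)
      qs <- c(qs, rq[ord])
      rs <- c(rs, rr[ord])
    }
  }
  coords <- cbind(q = as.integer(qs), r = as.integer(rs))
  xy <- hex_to_cartesian(coords[, 1], coords[, 2])
  circle <- as.integer(hex_dist0(coords[, 1], coords[, 2]) + 1L)
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  dirs <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 1L),
                c(-1L, 0L), c(0L, -1L), c(1L, -1L))
  adjacency <- lapply(seq_len(n), function(i) {
    nb <- paste(coords[i, 1] + dirs[, 1], coords[i, 2] + dirs[, 2])
    sort(unname(lookup[nb[nb %in% key]]))
  })
  structure(
    list(radius = radius, n = n, coords = coords, xy = xy,
         circle = circle, adjacency = adjacency, topology = "hex"),
    class = c("hexmap_spec", "map_spec")
  )
}

#' Build a rectangular sheet lattice specification
#'
#' An `nx` by `ny` square lattice with 8-connected (Moore) adjacency, used as
#' the output space of the sample landscape. Nodes are indexed row-major:
#' cell (row i, col j) has index `(i - 1) * nx + j`, embedded at Cartesian
#' `(j - 1, i - 1)`.
#'
#' @param nx,ny Positive integer lattice dimensions.
#' @return An object of class `sheetmap_spec` (and `map_spec`) with the same
#'   fields as [hex_map()] plus `nx`, `ny`; `coords` holds columns
#'   `col`, `row`.
#' @export
sheet_map <- function(nx, ny) {
  if (nx < 1 || ny < 1 || nx != round(nx) || ny != round(ny)) {
    stop("'nx' and 'ny' must be positive integers", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  rows <- rep(seq_len(ny), each = nx)
  cols <- rep(seq_len(nx), times = ny)
  n <- nx * ny
  adjacency <- lapply(seq_len(n), function(i) {
    nb <- which(abs(rows - rows[i]) <= 1L & abs(cols - cols[i]) <= 1L)
    sort(nb[nb != i])
  })
  structure(
    list(radius = max(nx, ny), n = n,
         coords = cbind(col = cols, row = rows),
         xy = cbind(x = as.numeric(cols - 1L), y = as.numeric(rows - 1L)),
         circle = rep(1L, n), adjacency = adjacency,
         topology = "sheet", nx = nx, ny = ny),
    class = c("sheetmap_spec", "map_spec")
  )
}

check_node_index <- function(i, spec) {
  if (any(i < 1L | i > spec$n | i != round(i))) {
    stop("node index out of range 1..", spec$n, call. = FALSE)
  }
  as.integer(i)
}

#' Output-space distance between two map nodes
#'
#' Euclidean distance between the Cartesian embeddings of nodes `i` and `j`.
#'
#' @param i,j Node indices.
#' @param spec A `map_spec`.
#' @return Non-negative numeric distance; 0 iff `i == j`.
#' @export
node_distance <- function(i, j, spec) {
  i <- check_node_index(i, spec)
  j <- check_node_index(j, spec)
  unname(sqrt((spec$xy[i, 1] - spec$xy[j, 1])^2 +
              (spec$xy[i, 2] - spec$xy[j, 2])^2))
}

#' Full output-space distance matrix of a map
#'
#' @param spec A `map_spec`.
#' @return Symmetric `n x n` matrix of pairwise node distances.
#' @export
node_distance_matrix <- function(spec) {
  as.matrix(stats::dist(spec$xy))
}

#' Export a map specification as TSV
#'
#' Writes `<prefix>_mapspec_nodes.tsv` (columns index, q, r, x, y, circle)
#' and `<prefix>_mapspec_edges.tsv` (columns from, to; each undirected
#' adjacency pair once with from < to).
#'
#' @param spec A `hexmap_spec`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_map_spec <- function(spec, prefix) {
  nodes <- data.frame(index = seq_len(spec$n),
                      q = spec$coords[, 1], r = spec$coords[, 2],
                      x = fmt_num(spec$xy[, 1]), y = fmt_num(spec$xy[, 2]),
                      circle = spec$circle)
  from <- rep(seq_len(spec$n), lengths(spec$adjacency))
  to <- unlist(spec$adjacency)
  keep <- from < to
  edges <- data.frame(from = from[keep], to = to[keep])
  f1 <- paste0(prefix, "_mapspec_nodes.tsv")
  f2 <- paste0(prefix, "_mapspec_edges.tsv")
  write_tsv(nodes, f1)
  write_tsv(edges, f2)
  invisible(c(f1, f2))
}

# radius back from node count (inverse of 1 + 3r(r-1)); NA if not a valid count
radius_from_node_count <- function(n) {
  r <- (3 + sqrt(12 * n - 3)) / 6
  if (abs(r - round(r)) > 1e-9) return(NA_integer_)
  as.integer(round(r))
}
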