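# Self-organising map training on a map_spec lattice: initialisation,
# neighbourhood kernels, batch and sequential learning.

#' Neighbourhood kernel value
#'
#' Weight given to a node at output-space distance `d` from the winning node,
#' with neighbourhood width `sigma`:
#' gaussian `exp(-d^2 / (2 sigma^2))`; bubble `1` if `d <= sigma` else `0`;
#' cutgaussian gaussian truncated at `d <= sigma`; epanechnikov
#' `max(0, 1 - (d/sigma)^2)`.
#'
#' @param kernel One of `"gaussian"`, `"bubble"`, `"cutgaussian"`,
#'   `"epanechnikov"`.
#' @param d Non-negative distance(s) in output space (vectorised).
#' @param sigma Positive neighbourhood width.
#' @return Weight(s) in `[0, 1]`.
#' @export
kernel_value <- function(kernel = c("gaussian", "bubble", "cutgaussian",
                                    "epanechnikov"),
                         d, sigma) {
  kernel <- match.arg(kernel)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  switch(kernel,
    gaussian = exp(-d^2 / (2 * sigma^2)),
    bubble = (d <= sigma) * 1,
    cutgaussian = exp(-d^2 / (2 * sigma^2)) * (d <= sigma),
    epanechnikov = pmax(1 - (d / sigma)^2, 0)
  )
}

#' Training configuration
#'
#' The schedule runs in ordered phases; within each phase the neighbourhood
#' width `sigma` (and, for the sequential algorithm, the learning rate
#' `alpha`) is interpolated linearly from its start to its end value over the
#' phase's epochs. The default two-phase schedule (built against the map at
#' training time when `phases = NULL`) is rough ordering (10 epochs,
#' `sigma: max(radius/2, 1) -> max(radius/8, 1)`, `alpha: 0.5 -> 0.05`)
#' followed by fine tuning (40 epochs, `sigma: max(radius/8, 1) -> 1`,
#' `alpha: 0.05 -> 0.01`). Fine tuning deliberately ends at `sigma = 1`:
#' shrinking the neighbourhood towards zero degenerates batch learning into
#' plain k-means, which destroys the topological ordering of the map and
#' leaves the U-matrix too wrinkled for local-minima seed finding.
#'
#' @param algorithm `"batch"` (default) or `"sequential"`.
#' @param kernel Neighbourhood kernel name; see [kernel_value()].
#' @param phases `NULL` for the default schedule, or a data frame with
#'   columns `epochs`, `sigma_start`, `sigma_end`, `alpha_start`, `alpha_end`.
#' @param init `"linear"` (default; principal-plane) or `"uniform"`.
#' @param seed Integer seed for any randomised step (uniform initialisation,
#'   sequential presentation order), or `NULL`.
#' @return A list of class `som_config`.
#' @export
som_config <- function(algorithm = c("batch", "sequential"),
                       kernel = c("gaussian", "bubble", "cutgaussian",
                                  "epanechnikov"),
                       phases = NULL,
                       init = c("linear", "uniform"),
                       seed = NULL) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  init <- match.arg(init)
  if (!is.null(phases)) check_phases(phases)
  structure(list(algorithm = algorithm, kernel = kernel, phases = phases,
                 init = init, seed = seed),
            class = "som_config")
}

check_phases <- function(phases) {
  need <- c("epochs", "sigma_start", "sigma_end", "alpha_start", "alpha_end")
  if (!is.data.frame(phases) || !all(need %in% names(phases))) {
    stop("'phases' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(phases$epochs < 1) || any(phases$epochs != round(phases$epochs))) {
    stop("phase 'epochs' must be positive integers", call. = FALSE)
  }
  if (any(phases$sigma_end <= 0) ||
      any(phases$sigma_start < phases$sigma_end)) {
    stop("each phase needs sigma_start >= sigma_end > 0", call. = FALSE)
  }
  invisible(phases)
}

#' Default two-phase training schedule for a map of given radius
#'
#' @param radius Map radius (hex maps) or half the larger lattice dimension
#'   (sheet maps).
#' @return Data frame of phases; see [som_config()].
#' @export
som_schedule <- function(radius) {
  mid <- max(radius / 8, 1)
  data.frame(
    epochs = c(10L, 40L),
    sigma_start = c(max(radius / 2, 1), mid),
    sigma_end = c(mid, 1),
    alpha_start = c(0.5, 0.05),
    alpha_end = c(0.05, 0.01)
  )
}

#' Default map radius for a given number of genes
#'
#' Smallest radius whose node count reaches `5 * sqrt(G)` (a standard
#' map-sizing heuristic), capped at 15.
#'
#' @param n_genes Number of input rows.
#' @return Integer radius.
#' @export
auto_radius <- function(n_genes) {
  target <- 5 * sqrt(n_genes)
  r <- 1L
  while (r < 15L && hex_node_count(r) < target) r <- r + 1L
  r
}

#' Initialise a codebook
#'
#' `"linear"` lays the prototypes on the plane spanned by the first two
#' principal directions of the (column-centred) input, with node coordinates
#' rescaled to the data's extent along each direction; if the input has rank
#' < 2 it falls back to uniform initialisation. `"uniform"` draws every
#' prototype component uniformly within that component's observed range.
#'
#' @param x Numeric genes x samples matrix (unique rownames).
#' @param spec A `map_spec`.
#' @param method `"linear"` or `"uniform"`.
#' @param seed Integer seed (used by uniform initialisation).
#' @return A `som_codebook`: list with `prototypes` (n_nodes x n_samples
#'   matrix) and `spec`.
#' @export
som_init <- function(x, spec, method = c("linear", "uniform"), seed = NULL) {
  x <- check_input_matrix(x)
  method <- match.arg(method)
  if (method == "linear") {
    proto <- init_linear(x, spec)
    if (is.null(proto)) {
      proto <- init_uniform(x, spec, seed)
    }
  } else {
    proto <- init_uniform(x, spec, seed)
  }
  colnames(proto) <- colnames(x)
  rownames(proto) <- seq_len(spec$n)
  new_codebook(proto, spec)
}

new_codebook <- function(prototypes, spec) {
  structure(list(prototypes = prototypes, spec = spec,
                 col_ids = colnames(prototypes)),
            class = "som_codebook")
}

init_linear <- function(x, spec) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8)
  if (nrow(x) < 2L || rank < 2L) return(NULL)
  # canonical sign: largest-magnitude loading positive, so the init (and
  # everything downstream) is invariant to input row order
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  v1 <- fix_sign(sv$v[, 1]); v2 <- fix_sign(sv$v[, 2])
  s1 <- as.vector(xc %*% v1); s2 <- as.vector(xc %*% v2)
  c1 <- rescale_to(spec$xy[, 1], range(s1))
  c2 <- rescale_to(spec$xy[, 2], range(s2))
  outer(c1, v1) + outer(c2, v2) + matrix(mu, spec$n, ncol(x), byrow = TRUE)
}

rescale_to <- function(v, rng) {
  span <- diff(range(v))
  if (span == 0) return(rep(mean(rng), length(v)))
  (v - min(v)) / span * diff(rng) + rng[1]
}

init_uniform <- function(x, spec, seed) {
  if (!is.null(seed)) set.seed(seed)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  proto <- matrix(stats::runif(spec$n * ncol(x)), spec$n, ncol(x))
  sweep(sweep(proto, 2, hi - lo, "*"), 2, lo, "+")
}

#' Best-matching unit of an input vector
#'
#' The winner minimises the Euclidean input-space distance between the vector
#' and the prototypes; all nodes within an absolute tolerance of 1e-12 of the
#' minimal distance are reported as ties, and the winner is the lowest-index
#' tie.
#'
#' @param codebook A `som_codebook`.
#' @param v Numeric vector of length `ncol(prototypes)`.
#' @return List with `winner` (node index) and `ties` (integer vector).
#' @export
find_bmu <- function(codebook, v) {
  m <- codebook$prototypes
  if (length(v) != ncol(m)) {
    stop("input vector has length ", length(v), ", expected ", ncol(m),
         call. = FALSE)
  }
  d <- unname(sqrt(colSums((t(m) - v)^2)))
  ties <- which(d - min(d) <= 1e-12)
  list(winner = ties[1L], ties = ties)
}

# winners only, vectorised over all rows
assign_bmus <- function(x, proto) {
  max.col(-cross_dist2(x, proto), ties.method = "first")
}

phase_interp <- function(start, end, e, epochs) {
  if (epochs == 1L) return(start)
  start + (end - start) * (e - 1) / (epochs - 1)
}

#' Train a self-organising map
#'
#' Runs the configured learning algorithm over the schedule and returns the
#' trained codebook together with the final gene-to-node mapping and the
#' per-epoch quantization-error trace.
#'
#' Batch learning replaces each prototype per epoch by the kernel-weighted
#' mean of all input rows, weighted by the output-space distance between each
#' row's best-matching node and the prototype's node; nodes receiving zero
#' total weight keep their previous prototype (with a warning). Sequential
#' learning presents rows one at a time in a seeded random order per epoch
#' and moves every prototype towards the presented row by
#' `alpha * kernel * (x - m)`.
#'
#' @param x Numeric genes x samples matrix; rownames are gene identifiers.
#' @param radius Map radius, or `NULL` to size the map via [auto_radius()].
#'   Ignored when `spec` is given.
#' @param spec Optional pre-built `map_spec`.
#' @param config A [som_config()].
#' @return A `som_fit`: list with `codebook` (`som_codebook`), `mapping`
#'   (`som_mapping`, see [hit_histogram()]) and `qe_trace` (numeric vector of
#'   per-epoch quantization errors).
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
#' fit <- som_train(x, radius = 3, config = som_config(seed = 1))
#' @export
som_train <- function(x, radius = NULL, spec = NULL,
                      config = som_config()) {
  x <- check_input_matrix(x)
  if (is.null(spec)) {
    if (is.null(radius)) radius <- auto_radius(nrow(x))
    spec <- hex_map(radius)
  }
  phases <- config$phases
  if (is.null(phases)) {
    r <- if (spec$topology == "hex") spec$radius
         else ceiling(max(spec$nx, spec$ny) / 2)
    phases <- som_schedule(r)
  }
  check_phases(phases)
  codebook <- som_init(x, spec, config$init, config$seed)
  res <- if (config$algorithm == "batch") {
    train_batch(x, codebook, phases, config$kernel)
  } else {
    train_sequential(x, codebook, phases, config$kernel, config$seed)
  }
  mapping <- hit_histogram(x, res$codebook)
  structure(list(codebook = res$codebook, mapping = mapping,
                 qe_trace = res$qe_trace, config = config, phases = phases),
            class = "som_fit")
}

train_batch <- function(x, codebook, phases, kernel) {
  spec <- codebook$spec
  proto <- codebook$prototypes
  dm <- node_distance_matrix(spec)
  qe <- numeric(0)
  starved <- FALSE
  for (p in seq_len(nrow(phases))) {
    ph <- phases[p, ]
    for (e in seq_len(ph$epochs)) {
      sigma <- phase_interp(ph$sigma_start, ph$sigma_end, e, ph$epochs)
      bmu <- assign_bmus(x, proto)
      cnt <- tabulate(bmu, nbins = spec$n)
      s <- matrix(0, spec$n, ncol(x))
      acc <- rowsum(x, group = bmu, reorder = TRUE)
      s[as.integer(rownames(acc)), ] <- acc
      k <- kernel_value(kernel, dm, sigma)
      numer <- k %*% s
      denom <- as.vector(k %*% cnt)
      upd <- denom > 0
      if (any(!upd)) starved <- TRUE
      proto[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
      qe <- c(qe, mean(sqrt(rowSums((x - proto[assign_bmus(x, proto), ,
                                               drop = FALSE])^2))))
    }
  }
  if (starved) {
    warning("some nodes received zero kernel weight in at least one epoch; ",
            "their prototypes were left unchanged", call. = FALSE)
  }
  list(codebook = new_codebook(proto, spec), qe_trace = qe)
}

train_sequential <- function(x, codebook, phases, kernel, seed) {
  spec <- codebook$spec
  proto <- codebook$prototypes
  dm <- node_distance_matrix(spec)
  g <- nrow(x)
  qe <- numeric(0)
  if (!is.null(seed)) set.seed(seed + 1L)
  for (p in seq_len(nrow(phases))) {
    ph <- phases[p, ]
    total <- ph$epochs * g
    t0 <- 0L
    for (e in seq_len(ph$epochs)) {
      ord <- sample.int(g)
      for (i in ord) {
        t0 <- t0 + 1L
        sigma <- phase_interp(ph$sigma_start, ph$sigma_end, t0, total)
        alpha <- phase_interp(ph$alpha_start, ph$alpha_end, t0, total)
        b <- which.min(colSums((t(proto) - x[i, ])^2))
        w <- alpha * kernel_value(kernel, dm[b, ], sigma)
        proto <- proto + w * (matrix(x[i, ], spec$n, ncol(x), byrow = TRUE) -
                              proto)
      }
      qe <- c(qe, mean(sqrt(rowSums((x - proto[assign_bmus(x, proto), ,
                                               drop = FALSE])^2))))
    }
  }
  list(codebook = new_codebook(proto, spec), qe_trace = qe)
}

#' Quantization error of a codebook on an input matrix
#'
#' Mean over input rows of the Euclidean distance from each row to its
#' best-matching prototype.
#'
#' @param x Numeric genes x samples matrix.
#' @param codebook A `som_codebook`.
#' @return Single non-negative number.
#' @export
quantization_error <- function(x, codebook) {
  x <- check_input_matrix(x)
  proto <- codebook$prototypes
  if (ncol(x) != ncol(proto)) {
    stop("dimension mismatch between input and codebook", call. = FALSE)
  }
  bmu <- assign_bmus(x, proto)
  mean(sqrt(rowSums((x - proto[bmu, , drop = FALSE])^2)))
}
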