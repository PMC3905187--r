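# Synthetic genes x samples matrices with planted cluster structure, plus
# matched overlay layers. Emulates the structure the method assumes: most
# genes are background noise around zero, against which a few coherent
# clusters stand out.

#' Generate a synthetic genes x samples matrix with planted clusters
#'
#' A fraction `background_fraction` of genes are pure noise,
#' `Normal(0, sigma_n^2)` per component. The remaining genes are split as
#' evenly as possible across `clusters` clusters; each cluster has a
#' centroid drawn once from `Normal(0, tau^2)` per component, and its genes
#' are the centroid plus `Normal(0, sigma_n^2)` noise. Clusters are
#' separable when `tau > sigma_n`.
#'
#' @param n_genes Total number of genes G.
#' @param n_samples Number of samples S.
#' @param clusters Number of planted clusters C (`n_genes >= clusters`).
#' @param background_fraction Fraction of background genes in `[0, 1)`
#'   (1 is accepted and yields all-background data).
#' @param tau Centroid scale.
#' @param sigma_n Noise scale.
#' @param seed Integer seed.
#' @return List with `matrix` (G x S, rownames `gene1..`), `labels` (integer
#'   per-gene true cluster, 0 = background) and `centroids` (C x S).
#' @export
simulate_genes <- function(n_genes = 600, n_samples = 6, clusters = 4,
                           background_fraction = 0.3, tau = 3,
                           sigma_n = 0.3, seed = NULL) {
  if (clusters < 1 || n_genes < clusters || n_samples < 1 ||
      background_fraction < 0 || background_fraction > 1 ||
      tau < 0 || sigma_n < 0) {
    stop("invalid synthetic-data specification", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_bg <- round(background_fraction * n_genes)
  n_cl <- n_genes - n_bg
  labels <- integer(n_genes)
  if (n_cl > 0L) {
    sizes <- diff(round(seq(0, n_cl, length.out = clusters + 1L)))
    labels[(n_bg + 1L):n_genes] <- rep(seq_len(clusters), times = sizes)
  }
  centroids <- matrix(stats::rnorm(clusters * n_samples, sd = tau),
                      clusters, n_samples)
  x <- matrix(stats::rnorm(n_genes * n_samples, sd = sigma_n),
              n_genes, n_samples)
  in_cl <- labels > 0L
  x[in_cl, ] <- x[in_cl, , drop = FALSE] + centroids[labels[in_cl], ,
                                                     drop = FALSE]
  dimnames(x) <- list(paste0("gene", seq_len(n_genes)),
                      paste0("sample", seq_len(n_samples)))
  list(matrix = x, labels = labels, centroids = centroids)
}

#' Generate an overlay column matched to planted cluster labels
#'
#' Logical mode emulates promoter-class indicator layers: a gene in one of
#' the designated clusters gets 1 with probability `p_in`, any other gene
#' with probability `p_out`. Numeric mode emulates an expression-level
#' layer: genes in a designated cluster are shifted by `shift`, on top of
#' standard-normal noise.
#'
#' @param labels Integer per-gene labels (0 = background), as from
#'   [simulate_genes()].
#' @param mode `"logical"` or `"numeric"`.
#' @param p_in,p_out Membership probabilities for logical mode.
#' @param clusters Designated cluster ids (default: cluster 1).
#' @param shift Mean shift for numeric mode.
#' @param seed Integer seed.
#' @return Numeric vector of length `length(labels)`, named like `labels`.
#' @export
simulate_overlay <- function(labels, mode = c("logical", "numeric"),
                             p_in = 0.9, p_out = 0.1, clusters = 1L,
                             shift = 2, seed = NULL) {
  mode <- match.arg(mode)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("'p_in' and 'p_out' must be probabilities", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- length(labels)
  inside <- labels %in% clusters
  y <- if (mode == "logical") {
    as.numeric(stats::runif(g) < ifelse(inside, p_in, p_out))
  } else {
    stats::rnorm(g) + shift * inside
  }
  names(y) <- names(labels)
  y
}
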