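# Overlay additional per-gene data layers onto a trained map:
# kernel-weighted accumulation normalised by kernel-weighted hits.

# per-node total tie weight: each gene contributes 1, split equally over its
# co-best-matching nodes
tie_weight_per_node <- function(mapping, n_nodes) {
  w <- numeric(n_nodes)
  idx <- rep(seq_along(mapping$ties), lengths(mapping$ties))
  nodes <- unlist(mapping$ties)
  contrib <- 1 / lengths(mapping$ties)[idx]
  acc <- rowsum(contrib, group = nodes)
  w[as.integer(rownames(acc))] <- acc
  w
}

#' Neighbourhood-kernel-weighted hit counts
#'
#' For each node `j`, sums over genes the kernel weight of the output-space
#' distance between the gene's best-matching node(s) and `j`; a gene with
#' several co-best nodes contributes an equal fractional share through each.
#' With the bubble kernel and `sigma < 1` this reduces to the plain (tie-
#' shared) hit histogram.
#'
#' @param mapping A `som_mapping` (from [hit_histogram()]).
#' @param kernel Kernel name; see [kernel_value()].
#' @param sigma Positive kernel width in output-space units.
#' @return Numeric vector of per-node weighted hits.
#' @export
weighted_hits <- function(mapping, kernel = "gaussian", sigma = 1) {
  spec <- mapping$spec
  k <- kernel_value(kernel, node_distance_matrix(spec), sigma)
  as.vector(k %*% tie_weight_per_node(mapping, spec$n))
}

#' Overlay additional per-gene data onto a trained map
#'
#' Accumulates each overlay column onto the map with the same per-gene
#' kernel weights as [weighted_hits()] and normalises the accumulated values
#' by the weighted hits, so that overlaying a constant column returns that
#' constant at every defined node. Nodes whose weighted hits fall below
#' `eps` are flagged undefined (`NA` values). Overlay rows must be a subset
#' of the training gene ids.
#'
#' @param mapping A `som_mapping` from training.
#' @param additional Numeric matrix over (a subset of) the training gene
#'   ids; columns may be numeric or 0/1 logical layers.
#' @param kernel,sigma Overlay kernel and width; the default width 1
#'   matches the terminal neighbourhood of the default training schedule.
#' @param eps Weighted-hits threshold below which a node is undefined.
#' @return An `overlay_result`: list with `values` (n_nodes x n_cols matrix,
#'   `NA` where undefined), `weighted_hits`, `undefined_mask`, `col_ids`
#'   and `spec`.
#' @export
overlay_data <- function(mapping, additional, kernel = "gaussian",
                         sigma = 1, eps = 1e-9) {
  spec <- mapping$spec
  additional <- check_input_matrix(additional, "additional")
  unknown <- setdiff(rownames(additional), names(mapping$bmu))
  if (length(unknown) > 0L) {
    stop("overlay rows not present in the training data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sub <- mapping$ties[rownames(additional)]
  idx <- rep(seq_along(sub), lengths(sub))
  nodes <- unlist(sub)
  contrib <- 1 / lengths(sub)[idx]
  # per-node accumulated weight and weighted data sums over overlay genes
  k <- kernel_value(kernel, node_distance_matrix(spec), sigma)
  tw <- numeric(spec$n)
  acc_w <- rowsum(contrib, group = nodes)
  tw[as.integer(rownames(acc_w))] <- acc_w
  sy <- matrix(0, spec$n, ncol(additional))
  acc_y <- rowsum(additional[idx, , drop = FALSE] * contrib, group = nodes)
  sy[as.integer(rownames(acc_y)), ] <- acc_y
  h <- as.vector(k %*% tw)
  a <- k %*% sy
  undefined <- h < eps
  values <- a / h
  values[undefined, ] <- NA_real_
  colnames(values) <- colnames(additional)
  rownames(values) <- seq_len(spec$n)
  structure(list(values = values, weighted_hits = h,
                 undefined_mask = undefined,
                 col_ids = colnames(additional), spec = spec,
                 kernel = kernel, sigma = sigma),
            class = "overlay_result")
}

#' Repackage an overlay result as a codebook
#'
#' The overlaid values form an artificial codebook in the dimension of the
#' overlay data, usable for sample-landscape training and component
#' reordering. Undefined nodes are imputed as the mean of their defined
#' adjacent nodes, iterated until every node is defined.
#'
#' @param result An `overlay_result`.
#' @return A `som_codebook` over the overlay columns.
#' @export
overlay_as_codebook <- function(result) {
  spec <- result$spec
  values <- result$values
  undef <- result$undefined_mask
  if (all(undef)) {
    stop("all nodes are undefined; nothing to impute", call. = FALSE)
  }
  while (any(undef)) {
    fixable <- which(undef & vapply(spec$adjacency,
                                    function(nb) any(!undef[nb]),
                                    logical(1)))
    if (length(fixable) == 0L) {
      stop("undefined nodes are disconnected from defined nodes",
           call. = FALSE)
    }
    newvals <- lapply(fixable, function(j) {
      nb <- spec$adjacency[[j]]
      colMeans(values[nb[!undef[nb]], , drop = FALSE])
    })
    for (i in seq_along(fixable)) values[fixable[i], ] <- newvals[[i]]
    undef[fixable] <- FALSE
  }
  rownames(values) <- seq_len(spec$n)
  new_codebook(values, spec)
}
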