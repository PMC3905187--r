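# Sample landscape: lay samples out on a small square lattice so that
# geometric proximity reflects profile similarity.

#' Sample-wise feature vectors from a codebook or input matrix
#'
#' Returns the transpose view: one feature vector per sample. For a codebook
#' the features are the map nodes; for an input matrix they are the genes.
#'
#' @param source A `som_codebook` or a numeric genes x samples matrix.
#' @return Numeric samples x features matrix with sample ids as rownames.
#' @export
sample_vectors <- function(source) {
  if (inherits(source, "som_codebook")) {
    t(source$prototypes)
  } else {
    t(check_input_matrix(source))
  }
}

#' Pairwise sample similarity / distance matrix
#'
#' Supported metrics: `pearson`, `spearman` (Pearson on average ranks),
#' `kendall` (tau-b), `euclidean`, `cityblock`, `cosine`, and
#' `mutual_information` (plug-in estimator on `ceiling(sqrt(F))` equal-width
#' bins per variable over each variable's observed range, in bits; the
#' diagonal is the discretised entropy H(X)). A zero-variance vector under a
#' correlation metric yields 0 with a warning.
#'
#' @param vectors Samples x features numeric matrix (e.g. from
#'   [sample_vectors()]); at least 2 features.
#' @param metric Metric name.
#' @return An object of class `similarity_matrix`: list with `values`
#'   (S x S symmetric matrix), `metric` and `ids`.
#' @export
similarity_matrix <- function(vectors,
                              metric = c("pearson", "spearman", "kendall",
                                         "euclidean", "cityblock", "cosine",
                                         "mutual_information")) {
  metric <- match.arg(metric)
  if (!is.matrix(vectors) || ncol(vectors) < 2L) {
    stop("'vectors' must be a matrix with at least 2 feature columns",
         call. = FALSE)
  }
  if (is.null(rownames(vectors))) {
    rownames(vectors) <- paste0("s", seq_len(nrow(vectors)))
  }
  vals <- switch(metric,
    pearson = ,
    spearman = ,
    kendall = safe_cor(vectors, metric),
    euclidean = as.matrix(stats::dist(vectors, method = "euclidean")),
    cityblock = as.matrix(stats::dist(vectors, method = "manhattan")),
    cosine = cosine_matrix(vectors),
    mutual_information = mi_matrix(vectors)
  )
  dimnames(vals) <- list(rownames(vectors), rownames(vectors))
  structure(list(values = vals, metric = metric, ids = rownames(vectors)),
            class = "similarity_matrix")
}

safe_cor <- function(vectors, metric) {
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance sample vector(s) under a correlation metric; ",
            "their correlations are set to 0", call. = FALSE)
  }
  ok <- sds > 0
  vals <- matrix(0, nrow(vectors), nrow(vectors))
  if (any(ok)) {
    vals[ok, ok] <- stats::cor(t(vectors[ok, , drop = FALSE]),
                               method = metric)
  }
  diag(vals) <- ifelse(ok, 1, 0)
  vals
}

cosine_matrix <- function(vectors) {
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) {
    warning("zero vector(s) under cosine similarity; set to 0",
            call. = FALSE)
  }
  nrm[nrm == 0] <- 1
  v <- vectors / nrm
  out <- tcrossprod(v)
  diag(out) <- as.numeric(sqrt(rowSums(vectors^2)) > 0)
  out
}

discretise <- function(v, bins) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(1L, length(v)))
  b <- findInterval(v, seq(rng[1], rng[2], length.out = bins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b)
}

mi_pair <- function(a, b, bins) {
  tab <- table(discretise(a, bins), discretise(b, bins))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

mi_matrix <- function(vectors) {
  s <- nrow(vectors)
  bins <- ceiling(sqrt(ncol(vectors)))
  vals <- matrix(0, s, s)
  for (i in seq_len(s)) {
    for (j in i:s) {
      vals[i, j] <- vals[j, i] <- mi_pair(vectors[i, ], vectors[j, ], bins)
    }
  }
  vals
}

#' Train the sample landscape
#'
#' Trains a small sheet-topology self-organising map (8-connected square
#' lattice of `ceiling(sqrt(S))` x `ceiling(S / nx)` cells, Euclidean output
#' distance) on per-sample feature vectors — either raw sample vectors or
#' the rows of a precomputed [similarity_matrix()], which makes the training
#' cost independent of the number of genes. Each sample is then placed at
#' its best-matching cell; when several samples collide on one cell, samples
#' are processed in order of decreasing best-matching margin (distance gap
#' between their best and second-best cells) and a colliding sample moves to
#' the nearest free cell (Euclidean, ties row-major).
#'
#' @param x Samples x features matrix, a `similarity_matrix`, or a
#'   `som_codebook` / genes x samples matrix (passed through
#'   [sample_vectors()]).
#' @param seed Integer seed for the training schedule.
#' @param config Optional [som_config()]; the default schedule is used when
#'   `NULL`.
#' @return A `sample_landscape`: list with `nx`, `ny`, `placement` (data
#'   frame sample/row/col) and `order` (display order of sample ids; see
#'   [reorder_components()]).
#' @export
train_landscape <- function(x, seed = NULL, config = NULL) {
  if (inherits(x, "similarity_matrix")) {
    feats <- x$values
    rownames(feats) <- x$ids
  } else if (inherits(x, "som_codebook")) {
    feats <- sample_vectors(x)
  } else {
    feats <- x
    if (is.null(rownames(feats))) {
      rownames(feats) <- paste0("s", seq_len(nrow(feats)))
    }
  }
  s <- nrow(feats)
  nx <- as.integer(ceiling(sqrt(s)))
  ny <- as.integer(ceiling(s / nx))
  spec <- sheet_map(nx, ny)
  if (s == 1L) {
    placement <- data.frame(sample = rownames(feats), row = 1L, col = 1L,
                            stringsAsFactors = FALSE)
    return(new_landscape(nx, ny, placement))
  }
  if (is.null(config)) config <- som_config(seed = seed)
  if (ncol(feats) == 1L) feats <- cbind(feats, feats) # degenerate 1-feature
  fit <- som_train(feats, spec = spec, config = config)
  proto <- fit$codebook$prototypes
  d <- sqrt(cross_dist2(feats, proto))
  bmu <- apply(d, 1, which.min)
  margin <- apply(d, 1, function(r) {
    sr <- sort(r, partial = 2)
    sr[2] - sr[1]
  })
  ord <- order(-margin, rownames(feats))
  cell_of <- rep(NA_integer_, s)
  taken <- logical(spec$n)
  for (i in ord) {
    b <- bmu[i]
    if (!taken[b]) {
      cell_of[i] <- b
    } else {
      free <- which(!taken)
      dd <- (spec$xy[free, 1] - spec$xy[b, 1])^2 +
            (spec$xy[free, 2] - spec$xy[b, 2])^2
      # ties row-major: free is already in row-major index order
      cell_of[i] <- free[which.min(dd)]
    }
    taken[cell_of[i]] <- TRUE
  }
  placement <- data.frame(sample = rownames(feats),
                          row = spec$coords[cell_of, "row"],
                          col = spec$coords[cell_of, "col"],
                          stringsAsFactors = FALSE)
  new_landscape(nx, ny, placement)
}

new_landscape <- function(nx, ny, placement) {
  ord <- order(placement$row, placement$col, placement$sample)
  structure(list(nx = nx, ny = ny, placement = placement,
                 order = placement$sample[ord]),
            class = "sample_landscape")
}

#' Display order of samples from a landscape
#'
#' Orders the codebook's samples by their landscape cell in row-major order
#' (row, then column), ties broken by sample id — the order in which
#' per-sample component maps are arranged around the landscape frame.
#'
#' @param codebook A `som_codebook` (possibly an overlay codebook).
#' @param landscape A `sample_landscape` over the same sample ids.
#' @return Character vector of sample ids in display order.
#' @export
reorder_components <- function(codebook, landscape) {
  ids <- codebook$col_ids
  if (!setequal(ids, landscape$placement$sample)) {
    stop("sample ids of the codebook and the landscape do not match",
         call. = FALSE)
  }
  landscape$order
}
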