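# Tabular input/output: canonical TSV (CSV accepted on read), lossless
# numeric round-trips at 1e-12.

#' Read a genes x samples matrix from a delimited file
#'
#' Expects one header row of sample identifiers and one leading column of
#' gene identifiers. Rows containing any non-numeric or missing cell are
#' dropped (a message reports the count); duplicate gene identifiers are an
#' error.
#'
#' @param path File path.
#' @param delimiter `"auto"` (sniff tab, else comma), `"tab"` or `"comma"`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(delimiter,
    tab = "\t", comma = ",",
    auto = if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  )
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = ""),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L || nrow(df) < 1L) {
    stop("matrix file needs a gene-id column plus at least one sample column",
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(as.character(col)),
           numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  bad <- apply(vals, 1L, anyNA)
  if (any(bad)) {
    message("dropped ", sum(bad),
            " row(s) with missing or non-numeric cells")
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("no usable rows in ", path, call. = FALSE)
  vals
}

#' Write results to TSV files
#'
#' Dispatches on the result class and writes one or more `<prefix>_*.tsv`
#' files. Numeric values are serialised with 15 significant digits and
#' round-trip within 1e-12. Output bytes are deterministic for fixed input.
#'
#' @param x A `som_fit`, `meta_clustering`, `sample_landscape` or
#'   `overlay_result`.
#' @param prefix Output path prefix.
#' @param ... Passed to methods (`meta_clustering` accepts `mapping` to also
#'   write per-gene cluster assignments).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, prefix, ...) UseMethod("write_results")

#' @export
write_results.som_fit <- function(x, prefix, ...) {
  cb <- x$codebook
  proto <- cb$prototypes
  cb_df <- data.frame(node = seq_len(nrow(proto)), check.names = FALSE)
  for (j in seq_len(ncol(proto))) cb_df[[colnames(proto)[j]]] <-
    fmt_num(proto[, j])
  f1 <- paste0(prefix, "_codebook.tsv")
  write_tsv(cb_df, f1)
  m <- x$mapping
  map_df <- data.frame(
    gene = names(m$bmu), bmu = unname(m$bmu),
    ties = vapply(m$ties, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  f2 <- paste0(prefix, "_mapping.tsv")
  write_tsv(map_df, f2)
  um <- umatrix(cb)
  stats_df <- data.frame(node = seq_len(cb$spec$n),
                         umatrix = fmt_num(um$values), hits = m$hits)
  f3 <- paste0(prefix, "_nodestats.tsv")
  write_tsv(stats_df, f3)
  invisible(c(f1, f2, f3, write_map_spec(cb$spec, prefix)))
}

#' @export
write_results.meta_clustering <- function(x, prefix, mapping = NULL, ...) {
  df <- data.frame(node = seq_along(x$labels), cluster = x$labels,
                   is_seed = as.integer(seq_along(x$labels) %in% x$seeds))
  f1 <- paste0(prefix, "_metaclusters.tsv")
  write_tsv(df, f1)
  out <- f1
  if (!is.null(mapping)) {
    gc <- gene_clusters(mapping, x)
    f2 <- paste0(prefix, "_geneclusters.tsv")
    write_tsv(data.frame(gene = names(gc), cluster = unname(gc),
                         stringsAsFactors = FALSE), f2)
    out <- c(out, f2)
  }
  invisible(out)
}

#' @export
write_results.sample_landscape <- function(x, prefix, ...) {
  p <- x$placement
  p$rank <- match(p$sample, x$order)
  f <- paste0(prefix, "_landscape.tsv")
  write_tsv(p[order(p$rank), ], f)
  invisible(f)
}

#' @export
write_results.overlay_result <- function(x, prefix, ...) {
  df <- data.frame(node = seq_len(x$spec$n),
                   weighted_hits = fmt_num(x$weighted_hits),
                   undefined = as.integer(x$undefined_mask))
  for (j in seq_along(x$col_ids)) {
    df[[x$col_ids[j]]] <- fmt_num(x$values[, j])
  }
  f <- paste0(prefix, "_overlay.tsv")
  write_tsv(df, f)
  invisible(f)
}

# readers used by the CLI to resume a workflow from files ---------------------

read_codebook <- function(prefix) {
  f <- paste0(prefix, "_codebook.tsv")
  if (!file.exists(f)) {
    stop("no trained codebook at '", f, "'; run 'train' first",
         call. = FALSE)
  }
  m <- read_matrix(f, "tab")
  r <- radius_from_node_count(nrow(m))
  if (is.na(r)) stop("codebook row count ", nrow(m),
                     " is not a valid supra-hexagonal node count",
                     call. = FALSE)
  new_codebook(m, hex_map(r))
}

read_mapping <- function(prefix, spec) {
  f <- paste0(prefix, "_mapping.tsv")
  if (!file.exists(f)) {
    stop("no mapping at '", f, "'; run 'train' first", call. = FALSE)
  }
  df <- utils::read.table(f, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  ties <- lapply(strsplit(df$ties, ","), as.integer)
  names(ties) <- df$gene
  structure(list(bmu = stats::setNames(df$bmu, df$gene), ties = ties,
                 hits = tabulate(df$bmu, nbins = spec$n), spec = spec),
            class = "som_mapping")
}
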