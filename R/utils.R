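# shared internal helpers

# 15 significant digits: enough for lossless round-trip at 1e-12 absolute
# on values of magnitude ~1
fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g", width = 1)
  out[is.na(x)] <- "NA"
  gsub(" ", "", out)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}

check_input_matrix <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L) {
    stop("'", what, "' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("'", what, "' must not contain missing or non-finite values",
         call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x))) {
    stop("row identifiers of '", what, "' must be unique", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("s", seq_len(ncol(x)))
  }
  x
}

# squared Euclidean distances between rows of x (G x D) and rows of m (M x D)
cross_dist2 <- function(x, m) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(m))) +
    outer(rep(1, nrow(x)), rowSums(m^2)) - 2 * tcrossprod(x, m)
  pmax(d2, 0)
}
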