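# Node-level statistics of a trained map and SVG rendering.

#' Per-node scalar field over a map
#'
#' @param values Numeric vector, one value per node.
#' @param spec The `map_spec` the values live on.
#' @param label Short text label (used in rendering).
#' @return An object of class `node_field`.
#' @export
node_field <- function(values, spec, label = "") {
  if (length(values) != spec$n) {
    stop("'values' must have one entry per node (", spec$n, ")",
         call. = FALSE)
  }
  structure(list(values = as.numeric(values), spec = spec, label = label),
            class = "node_field")
}

#' U-matrix (map distance) of a codebook
#'
#' Per node, the mean Euclidean input-space distance between its prototype
#' and the prototypes of its map-adjacent nodes. Low values mark cluster
#' interiors; high values mark boundaries. A radius-1 map has the single
#' value 0 by convention.
#'
#' @param codebook A `som_codebook`.
#' @return A [node_field()] labelled `"umatrix"`.
#' @export
umatrix <- function(codebook) {
  spec <- codebook$spec
  proto <- codebook$prototypes
  vals <- vapply(seq_len(spec$n), function(j) {
    nb <- spec$adjacency[[j]]
    if (length(nb) == 0L) return(0)
    mean(sqrt(rowSums((proto[nb, , drop = FALSE] -
                       matrix(proto[j, ], length(nb), ncol(proto),
                              byrow = TRUE))^2)))
  }, numeric(1))
  node_field(vals, spec, "umatrix")
}

#' Map each input row to its best-matching node
#'
#' Computes per-gene best-matching nodes (with ties at absolute tolerance
#' 1e-12) and the per-node hit counts. Hit counts always sum to the number
#' of input rows.
#'
#' @param x Numeric genes x samples matrix.
#' @param codebook A `som_codebook` over the same samples.
#' @return A `som_mapping`: list with `bmu` (named integer vector per gene),
#'   `ties` (list of integer vectors), `hits` (integer vector per node) and
#'   `spec`.
#' @export
hit_histogram <- function(x, codebook) {
  x <- check_input_matrix(x)
  proto <- codebook$prototypes
  if (ncol(x) != ncol(proto)) {
    stop("dimension mismatch between input and codebook", call. = FALSE)
  }
  d <- sqrt(cross_dist2(x, proto))
  dmin <- apply(d, 1, min)
  ties <- lapply(seq_len(nrow(x)),
                 function(i) which(d[i, ] - dmin[i] <= 1e-12))
  bmu <- vapply(ties, `[`, integer(1), 1L)
  names(bmu) <- rownames(x)
  names(ties) <- rownames(x)
  structure(list(bmu = bmu, ties = ties,
                 hits = tabulate(bmu, nbins = codebook$spec$n),
                 spec = codebook$spec),
            class = "som_mapping")
}

#' Per-node prototype patterns
#'
#' Returns the prototype vector of every node together with a `spans_zero`
#' flag, true when the pattern strictly crosses zero (`min < 0 < max`);
#' such patterns are drawn with the zero axis displayed.
#'
#' @param codebook A `som_codebook`.
#' @return List with `patterns` (the prototype matrix) and `spans_zero`
#'   (logical vector per node).
#' @export
node_patterns <- function(codebook) {
  proto <- codebook$prototypes
  list(patterns = proto,
       spans_zero = apply(proto, 1, min) < 0 & apply(proto, 1, max) > 0)
}

# linear colour scale helpers -------------------------------------------------

scale_colours <- function(values, diverging) {
  if (diverging) {
    lim <- max(abs(values), .Machine$double.eps)
    t <- (values / lim + 1) / 2
    ramp <- grDevices::colorRamp(c("#1f4e9c", "#ffffff", "#e67817"))
  } else {
    rng <- range(values)
    t <- if (diff(rng) == 0) rep(0.5, length(values)) else
      (values - rng[1]) / diff(rng)
    ramp <- grDevices::colorRamp(c("#fff5eb", "#7f2704"))
  }
  cols <- ramp(t)
  grDevices::rgb(cols[, 1], cols[, 2], cols[, 3], maxColorValue = 255)
}

svg_num <- function(x) sprintf("%.4f", x)

hexagon_points <- function(cx, cy) {
  # pointy-side-out hexagon with unit centre-to-centre spacing:
  # circumradius 1/sqrt(3), vertices at 30 + k*60 degrees
  ang <- (30 + 60 * 0:5) * pi / 180
  r <- 1 / sqrt(3)
  paste(svg_num(cx + r * cos(ang)), svg_num(cy + r * sin(ang)),
        sep = ",", collapse = " ")
}

#' Render a node scalar field as an SVG map
#'
#' Draws one hexagon per node at its Cartesian position, filled by a linear
#' colour scale (diverging and anchored at 0 when the field spans both signs,
#' sequential otherwise), plus a colour bar. Output is deterministic: the
#' same field yields byte-identical SVG.
#'
#' @param field A [node_field()] over a `hexmap_spec`.
#' @param file Output path for the SVG document.
#' @param scale_px Pixels per lattice unit.
#' @return Invisibly, `file`.
#' @export
render_map <- function(field, file, scale_px = 24) {
  spec <- field$spec
  values <- field$values
  diverging <- min(values) < 0 && max(values) > 0
  cols <- scale_colours(values, diverging)
  xy <- spec$xy * scale_px
  xy[, 2] <- -xy[, 2] # SVG y grows downward
  pad <- scale_px
  x0 <- min(xy[, 1]) - pad; x1 <- max(xy[, 1]) + pad
  y0 <- min(xy[, 2]) - pad; y1 <- max(xy[, 2]) + pad
  bar_w <- 18; bar_h <- (y1 - y0) * 0.6; bar_x <- x1 + 10
  width <- (x1 - x0) + bar_w + 70
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" viewBox=',
                   '"%s %s %s %s">'),
            svg_num(x0), svg_num(y0), svg_num(width), svg_num(y1 - y0)),
    sprintf('<title>%s</title>', field$label)
  )
  hexr <- scale_px # centre spacing scaled, so scale vertex radius too
  for (j in seq_len(spec$n)) {
    ang <- (30 + 60 * 0:5) * pi / 180
    pts <- paste(svg_num(xy[j, 1] + hexr / sqrt(3) * cos(ang)),
                 svg_num(xy[j, 2] + hexr / sqrt(3) * sin(ang)),
                 sep = ",", collapse = " ")
    lines <- c(lines,
               sprintf('<polygon points="%s" fill="%s" stroke="#555555" stroke-width="0.5"/>',
                       pts, cols[j]))
  }
  # colour bar: 32 stacked steps from min to max
  steps <- 32L
  vseq <- seq(min(values), max(values), length.out = steps)
  bcols <- scale_colours(vseq, diverging)
  step_h <- bar_h / steps
  for (k in seq_len(steps)) {
    yk <- y0 + (y1 - y0 - bar_h) / 2 + bar_h - k * step_h
    lines <- c(lines,
               sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                       svg_num(bar_x), svg_num(yk), svg_num(bar_w),
                       svg_num(step_h + 0.1), bcols[k]))
  }
  ytop <- y0 + (y1 - y0 - bar_h) / 2
  lines <- c(lines,
    sprintf('<text x="%s" y="%s" font-size="10">%s</text>',
            svg_num(bar_x + bar_w + 4), svg_num(ytop + 4),
            fmt_num(max(values))),
    sprintf('<text x="%s" y="%s" font-size="10">%s</text>',
            svg_num(bar_x + bar_w + 4), svg_num(ytop + bar_h),
            fmt_num(min(values))),
    '</svg>')
  writeLines(lines, file, sep = "\n")
  invisible(file)
}
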