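# V-plot matrices: 2-D binned densities of fragment-midpoint distance from
# an anchor (x) versus fragment length (y). The default grid is x in
# [-1000, +1000] bp at 5-bp bins (401 bins) by 400 consecutive 1-bp length
# bins starting at 25 bp, i.e. 160,400 bins total. X bins are centered on
# multiples of the bin width (k = round(d / x_bin), ties away from zero) so
# that negating all distances mirrors the matrix about x = 0 exactly.

#' Fragment midpoint (0-based, floor tie-break)
#' @param start,end 0-based half-open fragment coordinates (vectors ok)
#' @return midpoint position(s): `start + floor((end - start)/2)`
#' @export
fragment_midpoint <- function(start, end) {
  stopifnot(all(start < end))
  interval_midpoint(as.integer(start), as.integer(end))
}

# symmetric centered x-bin index: 1..(2K+1), bin centers k*x_bin
xbin_index <- function(d, x_bin, K) {
  k <- sign(d) * floor(abs(d) / x_bin + 0.5)
  k <- pmax(pmin(k, K), -K)
  as.integer(k + K + 1L)
}

#' Build a V-plot matrix around anchor sites
#'
#' For every (anchor, fragment) pair on the same chromosome, the signed
#' distance `d = midpoint - anchor` (negated for minus-strand anchors) is
#' computed; pairs with `|d| <= x_half_width` and fragment length in
#' `[y_min, y_max]` (closed) increment one bin. A fragment near two anchors
#' contributes to both.
#'
#' @param fs a [fragment_set()].
#' @param anchors anchor table (chrom, pos, strand, id), e.g. from
#'   [to_anchors()].
#' @param x_half_width half-width of the distance axis (bp).
#' @param x_bin x bin width (bp).
#' @param y_min,y_max fragment-length range (bp, inclusive).
#' @param y_bin y bin width (bp).
#' @return object of class `vplot_matrix`: `matrix` (rows = x bins, cols =
#'   y bins), bin centers/starts, `normalization` (`"counts"`), and
#'   `n_fragments` = total increments.
#' @export
build_vplot <- function(fs, anchors, x_half_width = 1000L, x_bin = 5L,
                        y_min = 25L, y_max = 424L, y_bin = 1L) {
  stopifnot(inherits(fs, "fragment_set"),
            x_half_width > 0, x_bin > 0, y_bin > 0, y_min <= y_max)
  a <- as_anchor_table(anchors)
  if (nrow(a) == 0) cf_stop("anchor list is empty")
  K <- as.integer(floor(x_half_width / x_bin + 0.5))
  n_x <- 2L * K + 1L
  n_y <- as.integer((y_max - y_min) %/% y_bin + 1L)
  mat <- matrix(0, nrow = n_x, ncol = n_y)
  fr <- fs$fragments
  mids <- fragment_midpoint(fr$start, fr$end)
  lens <- fr$end - fr$start
  len_ok <- lens >= y_min & lens <= y_max
  acc <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    sel <- fr$chrom == a$chrom[i] & len_ok
    if (!any(sel)) next
    d <- mids[sel] - a$pos[i]
    if (a$strand[i] == "-") d <- -d
    keep <- abs(d) <= x_half_width
    if (!any(keep)) next
    ix <- xbin_index(d[keep], x_bin, K)
    iy <- as.integer((lens[sel][keep] - y_min) %/% y_bin + 1L)
    acc[[i]] <- data.table::data.table(
      flat = (iy - 1L) * n_x + ix, w = fr$weight[sel][keep])
  }
  acc <- data.table::rbindlist(acc)
  if (nrow(acc)) {
    agg <- acc[, .(w = sum(w)), by = "flat"]
    mat[agg$flat] <- agg$w
  }
  structure(list(matrix = mat,
                 x_centers = (seq_len(n_x) - K - 1L) * x_bin,
                 y_starts = y_min + (seq_len(n_y) - 1L) * y_bin,
                 x_bin = as.integer(x_bin), y_bin = as.integer(y_bin),
                 x_half_width = as.integer(x_half_width),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 normalization = "counts", n_fragments = sum(mat)),
            class = "vplot_matrix")
}

#' @export
print.vplot_matrix <- function(x, ...) {
  cat(sprintf("<vplot_matrix> %d x-bins (%d bp) x %d y-bins (%d bp), %s, %g fragments\n",
              nrow(x$matrix), x$x_bin, ncol(x$matrix), x$y_bin,
              x$normalization, x$n_fragments))
  invisible(x)
}

#' Convert a counts V-plot to percent-of-fragments scale
#'
#' Each bin becomes `100 * count / contributing fragments`, so the matrix
#' totals 100: the value is the percentage of fragments used in
#' constructing the V-plot that fall in that bin.
#'
#' @param v a counts-normalized `vplot_matrix`.
#' @return the percent-normalized `vplot_matrix`.
#' @export
normalize_vplot <- function(v) {
  stopifnot(inherits(v, "vplot_matrix"))
  if (v$normalization != "counts") cf_stop("V-plot is already normalized")
  if (v$n_fragments <= 0) cf_stop("no contributing fragments; cannot normalize")
  v$matrix <- 100 * v$matrix / v$n_fragments
  v$normalization <- "percent"
  v
}

#' Export a V-plot matrix as TSV
#'
#' The matrix file is the contract: a commented header records the grid
#' parameters, normalization and fragment count; the body has one row per
#' fragment-length bin (first column = y bin start) and one column per
#' distance bin (header row = x bin centers). Percent matrices are written
#' in fixed 6-decimal format. [read_vplot()] inverts the format.
#'
#' @param v a `vplot_matrix`.
#' @param path output path.
#' @param comments extra comment lines.
#' @return `path`, invisibly.
#' @export
export_vplot <- function(v, path, comments = NULL) {
  stopifnot(inherits(v, "vplot_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(sprintf("# vplot x_half_width=%d x_bin=%d y_min=%d y_max=%d y_bin=%d normalization=%s n_fragments=%.6f",
                     v$x_half_width, v$x_bin, v$y_min, v$y_max, v$y_bin,
                     v$normalization, v$n_fragments), con)
  writeLines(paste(c("length", v$x_centers), collapse = "\t"), con)
  fmt <- if (v$normalization == "percent") function(z) sprintf("%.6f", z)
         else function(z) format(z, digits = 15, scientific = FALSE, trim = TRUE)
  for (j in seq_along(v$y_starts)) {
    writeLines(paste(c(v$y_starts[j], fmt(v$matrix[, j])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a V-plot matrix written by [export_vplot()]
#' @param path TSV file.
#' @return a `vplot_matrix`.
#' @export
read_vplot <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# vplot ", lines, value = TRUE)
  if (length(hdr) != 1) cf_stop("not a V-plot matrix file: ", path)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.a-z]+", hdr))[[1]]
  pars <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  body <- lines[!grepl("^#", lines)]
  tab <- data.table::fread(text = body, sep = "\t", header = TRUE)
  mat <- t(as.matrix(tab[, -1]))
  dimnames(mat) <- NULL
  v <- structure(list(
    matrix = mat,
    x_centers = as.integer(names(tab)[-1]),
    y_starts = tab[[1]],
    x_bin = as.integer(pars[["x_bin"]]), y_bin = as.integer(pars[["y_bin"]]),
    x_half_width = as.integer(pars[["x_half_width"]]),
    y_min = as.integer(pars[["y_min"]]), y_max = as.integer(pars[["y_max"]]),
    normalization = pars[["normalization"]],
    n_fragments = as.numeric(pars[["n_fragments"]])),
    class = "vplot_matrix")
  v
}
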