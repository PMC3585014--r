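#' Construct a per-base-pair genomic track
#'
#' A genomic track holds one numeric vector per chromosome at a fixed
#' resolution (default 1 bp). `NA` marks masked positions that carry no
#' numeric meaning (e.g. zero coverage in both IP and input for a log-ratio
#' track); masked positions are excluded from every downstream average.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param chrom_lengths named integer chromosome lengths (bp). Defaults to
#'   `resolution * length(values[[i]])`.
#' @param semantics value-semantics label: `"counts/bp"`, `"log2-ratio"` or
#'   `"metric"`.
#' @param resolution bin width in bp (1 = per-base).
#' @return an object of class `genomic_track`.
#' @export
genomic_track <- function(values, chrom_lengths = NULL,
                          semantics = c("counts/bp", "log2-ratio", "metric"),
                          resolution = 1L) {
  semantics <- match.arg(semantics)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    cf_stop("track values must be a named list (one vector per chromosome)")
  }
  values <- lapply(values, as.numeric)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(as.integer(lengths(values) * resolution),
                              names(values))
  } else {
    chrom_lengths <- setNames(as.integer(chrom_lengths[names(values)]),
                              names(values))
    expect_bins <- ceiling(chrom_lengths / resolution)
    if (any(lengths(values) != expect_bins)) {
      cf_stop("track vector length must equal ceiling(chrom length / resolution)")
    }
  }
  structure(list(values = values, chrom_lengths = chrom_lengths,
                 semantics = semantics, resolution = as.integer(resolution)),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat(sprintf("<genomic_track> %s @ %d bp, %d chromosome(s), %.0f masked bin(s)\n",
              x$semantics, x$resolution, length(x$values),
              sum(vapply(x$values, function(v) sum(is.na(v)), 0))))
  invisible(x)
}

track_chroms <- function(track) names(track$values)

#' Write a track as bedGraph
#'
#' Runs of equal value are merged; masked (`NA`) bins are omitted. Optional
#' `comments` are written as leading `#` lines.
#' @param track a [genomic_track()]
#' @param path output path
#' @param comments character vector of comment lines (without `#`)
#' @return `path`, invisibly
#' @export
write_track_bedgraph <- function(track, path, comments = NULL) {
  stopifnot(inherits(track, "genomic_track"))
  res <- track$resolution
  recs <- lapply(track_chroms(track), function(ch) {
    v <- track$values[[ch]]
    r <- S4Vectors::Rle(v)
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends_bin <- cumsum(rl)
    starts_bin <- ends_bin - rl + 1L
    keep <- !is.na(rv)
    if (!any(keep)) return(NULL)
    data.table::data.table(
      chrom = ch,
      start = (starts_bin[keep] - 1L) * res,
      end = pmin(ends_bin[keep] * res, track$chrom_lengths[[ch]]),
      value = rv[keep])
  })
  recs <- data.table::rbindlist(recs)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  if (nrow(recs)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", recs$chrom, recs$start, recs$end,
                       format(recs$value, digits = 15, scientific = FALSE,
                              trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a per-bp track
#'
#' Positions not covered by any record are masked (`NA`).
#' @param path bedGraph file
#' @param chrom_lengths named chromosome lengths (bp); required, every record
#'   must fall on a listed chromosome.
#' @param semantics value-semantics label for the resulting track
#' @return a [genomic_track()] at 1 bp resolution
#' @export
read_track_bedgraph <- function(path, chrom_lengths,
                                semantics = c("counts/bp", "log2-ratio", "metric")) {
  semantics <- match.arg(semantics)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(chrom_lengths))
  if (length(unknown)) {
    cf_stop("bedGraph chromosome(s) absent from length table: ",
            paste(unknown, collapse = ", "))
  }
  values <- lapply(names(chrom_lengths), function(ch) {
    v <- rep(NA_real_, chrom_lengths[[ch]])
    sel <- chroms == ch
    if (any(sel)) {
      s <- GenomicRanges::start(gr)[sel]  # 1-based
      e <- GenomicRanges::end(gr)[sel]
      sc <- S4Vectors::mcols(gr)$score[sel]
      for (i in seq_along(s)) v[s[i]:e[i]] <- sc[i]
    }
    v
  })
  names(values) <- names(chrom_lengths)
  genomic_track(values, chrom_lengths = chrom_lengths, semantics = semantics)
}
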