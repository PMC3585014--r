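#' Construct a fragment set
#'
#' A fragment set is the package's container for paired-end MNase protection
#' fragments: each record is the single genomic interval protected from
#' digestion (the span of the sequenced pair), in the 0-based half-open
#' convention used throughout the package. Sample metadata records the sample
#' name, its role (`"IP"` or `"input"`) and an optional digestion label
#' (e.g. `"2.5min"` / `"10min"`).
#'
#' @param fragments data.frame/data.table with columns `chrom` (character),
#'   `start`, `end` (0-based half-open integers) and optionally `weight`
#'   (positive count, default 1).
#' @param chrom_lengths optional named integer vector of chromosome lengths
#'   (bp). When supplied, fragments must lie within bounds.
#' @param name sample name.
#' @param role `"IP"` or `"input"`.
#' @param digestion free-form digestion label (e.g. `"2.5min"`).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, chrom_lengths = NULL, name = "sample",
                         role = c("input", "IP"), digestion = NA_character_) {
  role <- match.arg(role)
  fr <- data.table::as.data.table(fragments)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(fr))) {
    cf_stop("fragments must have columns chrom, start, end")
  }
  if (!"weight" %in% names(fr)) fr[, weight := 1L]
  fr <- fr[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), weight = as.numeric(weight))]
  if (nrow(fr) > 0) {
    if (any(!is.finite(fr$start)) || any(!is.finite(fr$end))) {
      cf_stop("non-finite fragment coordinates")
    }
    bad <- which(fr$start < 0L | fr$start >= fr$end)
    if (length(bad)) {
      cf_stop("invalid fragment interval(s) at row(s) ",
              paste(head(bad, 5), collapse = ", "),
              ": require 0 <= start < end")
    }
    if (any(fr$weight <= 0)) cf_stop("fragment weights must be positive")
    if (!is.null(chrom_lengths)) {
      if (is.null(names(chrom_lengths))) cf_stop("chrom_lengths must be named")
      unknown <- setdiff(unique(fr$chrom), names(chrom_lengths))
      if (length(unknown)) {
        cf_stop("fragments on chromosome(s) absent from length table: ",
                paste(unknown, collapse = ", "))
      }
      over <- which(fr$end > chrom_lengths[fr$chrom])
      if (length(over)) {
        cf_stop("fragment(s) extend beyond chromosome end at row(s) ",
                paste(head(over, 5), collapse = ", "))
      }
    }
  }
  structure(
    list(fragments = fr,
         chrom_lengths = if (is.null(chrom_lengths)) NULL else
           setNames(as.integer(chrom_lengths), names(chrom_lengths)),
         metadata = list(name = name, role = role, digestion = digestion)),
    class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<fragment_set> %s (%s%s): %d fragments on %d chromosome(s)\n",
              md$name, md$role,
              if (is.na(md$digestion)) "" else paste0(", ", md$digestion),
              nrow(x$fragments), length(unique(x$fragments$chrom))))
  if (nrow(x$fragments)) {
    lens <- fragment_lengths(x)
    cat(sprintf("  lengths: %d-%d bp (median %g)\n",
                min(lens), max(lens), stats::median(lens)))
  }
  invisible(x)
}

#' Fragment lengths (bp) of a fragment set
#' @param fs a `fragment_set`
#' @return integer vector of protected-interval lengths
#' @export
fragment_lengths <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  fs$fragments$end - fs$fragments$start
}

#' Number of fragments in a set
#' @param fs a `fragment_set`
#' @return integer count of records
#' @export
n_fragments <- function(fs) nrow(fs$fragments)

#' Drop duplicate fragment intervals
#'
#' Duplicate protections legitimately recur in MNase data and are retained by
#' default everywhere; this helper deduplicates identical (chrom, start, end)
#' records for users who want it.
#' @param fs a `fragment_set`
#' @return a `fragment_set` with one record per distinct interval
#' @export
deduplicate_fragments <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  fs$fragments <- unique(fs$fragments, by = c("chrom", "start", "end"))
  fs
}

# Internal: fragment set -> GRanges (1-based closed) for range machinery.
fragments_granges <- function(fs) {
  fr <- fs$fragments
  gr <- GenomicRanges::GRanges(
    seqnames = fr$chrom,
    ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end))
  S4Vectors::mcols(gr)$weight <- fr$weight
  gr
}

# Internal validator for anchor tables: chrom, pos (0-based), strand, id.
as_anchor_table <- function(anchors) {
  a <- data.table::as.data.table(anchors)
  if (!all(c("chrom", "pos") %in% names(a))) {
    cf_stop("anchors must have columns chrom and pos")
  }
  if (!"strand" %in% names(a)) a[, strand := "."]
  if (!"id" %in% names(a)) a[, id := as.character(seq_len(.N))]
  a[, .(chrom = as.character(chrom), pos = as.integer(pos),
        strand = as.character(strand), id = as.character(id))]
}
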