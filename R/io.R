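# Standard-format I/O. Internal convention is 0-based half-open everywhere;
# BED dialects are honored on disk (BED is already 0-based half-open,
# bedGraph likewise; FASTA via Biostrings).

read_tab_lines <- function(path) {
  if (!file.exists(path)) cf_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

parse_int_field <- function(x, lineno, what) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out))
  if (length(bad)) {
    cf_stop("malformed ", what, " at line ", lineno[bad[1]],
            ": '", x[bad[1]], "' is not an integer")
  }
  out
}

#' Read paired-end fragments from BED3 or BEDPE
#'
#' BED3 records are taken directly as protected intervals. BEDPE mate pairs
#' are collapsed to the spanning interval `min(start1, start2)` to
#' `max(end1, end2)`; pairs whose mates map to different chromosomes are
#' skipped and the skip count reported (attribute `n_skipped` and a message).
#' All other malformed lines are hard errors naming the line number: parsing
#' is total, nothing is dropped silently.
#'
#' @param path file path.
#' @param format `"BED3"` or `"BEDPE"`.
#' @param chrom_lengths optional named lengths for bounds checking.
#' @inheritParams fragment_set
#' @return a [fragment_set()]; attribute `n_skipped` counts skipped
#'   cross-chromosome BEDPE records.
#' @export
read_fragments <- function(path, format = c("BED3", "BEDPE"),
                           chrom_lengths = NULL, name = basename(path),
                           role = c("input", "IP"),
                           digestion = NA_character_) {
  format <- match.arg(format)
  role <- match.arg(role)
  tl <- read_tab_lines(path)
  nf <- lengths(tl$fields)
  need <- if (format == "BED3") 3L else 6L
  short <- which(nf < need)
  if (length(short)) {
    cf_stop("malformed ", format, " record at line ", tl$lineno[short[1]],
            ": expected >= ", need, " tab-separated fields, got ",
            nf[short[1]])
  }
  n_skipped <- 0L
  if (format == "BED3") {
    fr <- data.table::data.table(
      chrom = vapply(tl$fields, `[[`, "", 1L),
      start = parse_int_field(vapply(tl$fields, `[[`, "", 2L), tl$lineno, "start"),
      end = parse_int_field(vapply(tl$fields, `[[`, "", 3L), tl$lineno, "end"))
  } else {
    c1 <- vapply(tl$fields, `[[`, "", 1L)
    c2 <- vapply(tl$fields, `[[`, "", 4L)
    s1 <- parse_int_field(vapply(tl$fields, `[[`, "", 2L), tl$lineno, "start1")
    e1 <- parse_int_field(vapply(tl$fields, `[[`, "", 3L), tl$lineno, "end1")
    s2 <- parse_int_field(vapply(tl$fields, `[[`, "", 5L), tl$lineno, "start2")
    e2 <- parse_int_field(vapply(tl$fields, `[[`, "", 6L), tl$lineno, "end2")
    same <- c1 == c2
    n_skipped <- sum(!same)
    if (n_skipped > 0) {
      message("read_fragments: skipped ", n_skipped,
              " BEDPE record(s) with mates on different chromosomes")
    }
    fr <- data.table::data.table(
      chrom = c1[same],
      start = pmin(s1[same], s2[same]),
      end = pmax(e1[same], e2[same]))
  }
  fs <- fragment_set(fr, chrom_lengths = chrom_lengths, name = name,
                     role = role, digestion = digestion)
  attr(fs, "n_skipped") <- n_skipped
  fs
}

#' Write a fragment set as BED3
#' @param fs a [fragment_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fragments <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  data.table::fwrite(fs$fragments[, .(chrom, start, end)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read interval features from BED6
#'
#' @param path BED6 file (6 tab-separated columns: chrom, start, end, name,
#'   score, strand).
#' @param feature_class class label attached to every record (e.g. `"NDR"`,
#'   `"TFBS"`, `"ORF"`, `"centromere"`); defaults to the file's name column
#'   being left as-is with class `NA`.
#' @return data.table with columns chrom, start, end, name, score, strand,
#'   class_label (0-based half-open).
#' @export
read_features <- function(path, feature_class = NA_character_) {
  tl <- read_tab_lines(path)
  nf <- lengths(tl$fields)
  short <- which(nf < 6L)
  if (length(short)) {
    cf_stop("malformed BED6 record at line ", tl$lineno[short[1]],
            ": expected 6 fields, got ", nf[short[1]])
  }
  ft <- data.table::data.table(
    chrom = vapply(tl$fields, `[[`, "", 1L),
    start = parse_int_field(vapply(tl$fields, `[[`, "", 2L), tl$lineno, "start"),
    end = parse_int_field(vapply(tl$fields, `[[`, "", 3L), tl$lineno, "end"),
    name = vapply(tl$fields, `[[`, "", 4L),
    score = suppressWarnings(as.numeric(vapply(tl$fields, `[[`, "", 5L))),
    strand = vapply(tl$fields, `[[`, "", 6L),
    class_label = feature_class)
  bad <- which(ft$start >= ft$end)
  if (length(bad)) {
    cf_stop("invalid interval (start >= end) at line ", tl$lineno[bad[1]])
  }
  ft
}

#' Write interval features as BED6
#' @param features feature table as returned by [read_features()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_features <- function(features, path) {
  ft <- data.table::as.data.table(features)
  if (!"name" %in% names(ft)) ft[, name := "."]
  if (!"score" %in% names(ft)) ft[, score := 0]
  if (!"strand" %in% names(ft)) ft[, strand := "."]
  data.table::fwrite(
    ft[, .(chrom, start, end, name, score, strand)], path,
    sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Convert interval features to anchor sites
#'
#' Anchor extraction conventions (0-based positions):
#' * `midpoint`: `start + floor((end - start)/2)`;
#' * `five_prime`: `start` on the + strand, `end - 1` on the - strand;
#' * `three_prime`: mirrored (`end - 1` on +, `start` on -).
#'
#' @param features feature table (chrom, start, end, strand, name).
#' @param mode one of `"midpoint"`, `"five_prime"`, `"three_prime"`.
#' @return data.table of anchors: chrom, pos, strand, id.
#' @export
to_anchors <- function(features, mode = c("midpoint", "five_prime", "three_prime")) {
  mode <- match.arg(mode)
  ft <- data.table::as.data.table(features)
  if (!"strand" %in% names(ft)) ft[, strand := "."]
  if (mode != "midpoint" && any(!ft$strand %in% c("+", "-"))) {
    cf_stop("mode '", mode, "' requires stranded features (+/-)")
  }
  pos <- switch(mode,
    midpoint = interval_midpoint(ft$start, ft$end),
    five_prime = ifelse(ft$strand == "+", ft$start, ft$end - 1L),
    three_prime = ifelse(ft$strand == "+", ft$end - 1L, ft$start))
  data.table::data.table(
    chrom = ft$chrom, pos = as.integer(pos), strand = ft$strand,
    id = if ("name" %in% names(ft)) as.character(ft$name)
         else as.character(seq_len(nrow(ft))))
}

#' Read a genome FASTA into a named sequence map
#' @param path FASTA file
#' @return named `Biostrings::DNAStringSet`
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) cf_stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a sequence map as FASTA
#' @param seqs named `DNAStringSet` (or named character vector)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a gene metric table (TSV)
#'
#' Header is required; the first column must be `gene_id`, remaining columns
#' are named numeric metrics (e.g. expression, turnover, txn_rate).
#' @param path TSV file
#' @return data.table keyed by gene_id
#' @export
read_metric_table <- function(path) {
  mt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(mt)[1] != "gene_id") {
    cf_stop("metric table must have 'gene_id' as its first column")
  }
  mt[, gene_id := as.character(gene_id)]
  mt
}

#' Write a gene metric table (TSV with header)
#' @param metrics data.frame with gene_id first
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metric_table <- function(metrics, path) {
  data.table::fwrite(data.table::as.data.table(metrics), path, sep = "\t")
  invisible(path)
}
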