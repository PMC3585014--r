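# Sequence composition (position frequency matrices, A+T content) and
# trinucleotide DNA bendability scoring with windowed smoothing and group
# comparison.

#' Load a trinucleotide bendability scale
#'
#' A scale maps each of the 64 trinucleotides to a dimensionless bendability
#' value. The packaged default is the DNase I-derived consensus trinucleotide
#' bendability table (strand-symmetric: a trinucleotide and its reverse
#' complement share one value); any 64-entry TSV (`trinucleotide<TAB>value`)
#' can be supplied instead.
#'
#' @param path TSV file with columns trinucleotide, value; `NULL` loads the
#'   packaged consensus table.
#' @return named numeric vector of length 64 (class `bendability_scale`).
#' @export
read_bendability_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bendability_consensus.tsv",
                        package = "chromfrag", mustWork = TRUE)
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  sc <- setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  tri <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = ""))
  if (!setequal(names(sc), tri) || length(sc) != 64) {
    cf_stop("bendability scale must have exactly one value per trinucleotide (64 entries)")
  }
  if (any(!is.finite(sc))) cf_stop("bendability values must be finite")
  structure(sc[tri], class = "bendability_scale")
}

#' @rdname read_bendability_scale
#' @export
default_bendability_scale <- function() read_bendability_scale(NULL)

extract_seq <- function(genome, chrom, start, end) {
  # 0-based half-open -> Biostrings 1-based closed
  as.character(Biostrings::subseq(genome$seq[[chrom]], start + 1L, end))
}

#' Position frequency matrix around anchor sites
#'
#' Counts A/C/G/T at each position of the `2*flank + 1` bp window centered
#' on each anchor; minus-strand anchors contribute reverse-complemented
#' windows. Ambiguous bases are excluded from the four base rows and
#' tallied separately. Anchors whose window exceeds the sequence bounds are
#' skipped and counted.
#'
#' @param genome a `cf_genome` (or any list with a named `DNAStringSet` in
#'   `$seq`).
#' @param anchors anchor table (chrom, pos, strand, id).
#' @param flank window half-width (bp).
#' @return object of class `pfm`: `counts` (4 x width matrix, rows ACGT),
#'   `ambiguous` (per-position count), `at_fraction` (per-position
#'   (A+T)/(A+C+G+T)), `offset`, `n_sequences`, `n_skipped`.
#' @export
pfm_from_anchors <- function(genome, anchors, flank = 200L) {
  a <- as_anchor_table(anchors)
  if (!nrow(a)) cf_stop("anchor list is empty")
  width <- 2L * flank + 1L
  lens <- setNames(Biostrings::width(genome$seq), names(genome$seq))
  ok <- a$pos - flank >= 0L & a$pos + flank < lens[a$chrom]
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message("pfm_from_anchors: skipped ", n_skipped,
            " anchor(s) whose window exceeds the sequence bounds")
  }
  a <- a[ok]
  if (!nrow(a)) cf_stop("no anchor window fits inside the sequence")
  wins <- vapply(seq_len(nrow(a)), function(i) {
    extract_seq(genome, a$chrom[i], a$pos[i] - flank, a$pos[i] + flank + 1L)
  }, "")
  ss <- Biostrings::DNAStringSet(wins)
  neg <- a$strand == "-"
  if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
  cm <- Biostrings::consensusMatrix(ss, baseOnly = TRUE)
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  ambiguous <- cm["other", ]
  tot <- colSums(counts)
  structure(list(counts = counts, ambiguous = unname(ambiguous),
                 at_fraction = unname((counts["A", ] + counts["T", ]) / tot),
                 offset = -flank:flank, n_sequences = nrow(a),
                 n_skipped = n_skipped),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d positions x %d sequences (mean A+T %.3f)\n",
              ncol(x$counts), x$n_sequences, mean(x$at_fraction)))
  invisible(x)
}

#' Export a position frequency matrix as TSV
#'
#' Columns: offset, A, C, G, T, ambiguous, at_fraction -- a layout common
#' logo renderers accept.
#' @param p a `pfm`.
#' @param path output path.
#' @param comments extra comment lines.
#' @return `path`, invisibly.
#' @export
export_pfm <- function(p, path, comments = NULL) {
  con <- file(path, "w")
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  close(con)
  dt <- data.table::data.table(
    offset = p$offset, A = p$counts["A", ], C = p$counts["C", ],
    G = p$counts["G", ], T = p$counts["T", ], ambiguous = p$ambiguous,
    at_fraction = round(p$at_fraction, 6))
  data.table::fwrite(dt, path, sep = "\t", append = !is.null(comments),
                     col.names = TRUE)
  invisible(path)
}

#' Windowed DNA bendability profile of one sequence
#'
#' Each trinucleotide's scale value is anchored to its central base (so the
#' first and last positions carry no raw value); the profile value at
#' position p is the mean of the raw values inside the `window` bp window
#' centered at p. Trinucleotides containing ambiguous bases are excluded
#' from the window mean; positions whose window does not fit entirely
#' inside the sequence are `NA`.
#'
#' @param sequence character string or `DNAString` (length >= window).
#' @param scale a [read_bendability_scale()] result.
#' @param window odd window size in bp (default 39).
#' @return numeric vector (one value per position, 1-based; `NA` where
#'   undefined).
#' @export
bendability_profile <- function(sequence, scale = default_bendability_scale(),
                                window = 39L) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  if (window %% 2L == 0L) cf_stop("window must be odd")
  if (L < window) cf_stop("sequence shorter than window")
  raw <- rep(NA_real_, L)
  if (L >= 3) {
    tris <- substring(seq, 1:(L - 2), 3:L)
    raw[2:(L - 1)] <- unname(scale[tris])   # NA for ambiguous trinucleotides
  }
  h <- (window - 1L) %/% 2L
  ok <- !is.na(raw)
  csum <- c(0, cumsum(ifelse(ok, raw, 0)))
  cnum <- c(0, cumsum(as.numeric(ok)))
  prof <- rep(NA_real_, L)
  centers <- (h + 1L):(L - h)
  lo <- centers - h
  hi <- centers + h
  sums <- csum[hi + 1L] - csum[lo]
  ns <- cnum[hi + 1L] - cnum[lo]
  prof[centers] <- ifelse(ns > 0, sums / ns, NA_real_)
  prof
}

#' Compare mean bendability between two region classes
#'
#' Scores every region with [bendability_profile()], summarizes each by the
#' mean of its defined profile values, and compares the two classes with a
#' two-sided Welch t-test. Regions shorter than the window are excluded
#' with a counted message.
#'
#' @param regions_a,regions_b interval tables (chrom, start, end), >= 2
#'   scoreable regions each.
#' @param genome a `cf_genome` (or list with `$seq` `DNAStringSet`).
#' @param scale bendability scale.
#' @param window odd smoothing window (bp).
#' @return list: `mean_difference` (a minus b), `p_value`, `statistic`,
#'   per-class means and per-region tables.
#' @export
compare_region_bendability <- function(regions_a, regions_b, genome,
                                       scale = default_bendability_scale(),
                                       window = 39L) {
  score_class <- function(regions, label) {
    rg <- data.table::as.data.table(regions)
    short <- rg$end - rg$start < window
    if (any(short)) {
      message("compare_region_bendability: excluded ", sum(short),
              " region(s) shorter than the window in class ", label)
      rg <- rg[!short]
    }
    vapply(seq_len(nrow(rg)), function(i) {
      prof <- bendability_profile(
        extract_seq(genome, rg$chrom[i], rg$start[i], rg$end[i]),
        scale = scale, window = window)
      mean(prof, na.rm = TRUE)
    }, 0)
  }
  ma <- score_class(regions_a, "A")
  mb <- score_class(regions_b, "B")
  if (length(ma) < 2 || length(mb) < 2) {
    cf_stop("each class needs >= 2 regions at least as long as the window")
  }
  tt <- stats::t.test(ma, mb, var.equal = FALSE, alternative = "two.sided")
  list(mean_difference = mean(ma) - mean(mb),
       p_value = tt$p.value, statistic = unname(tt$statistic),
       mean_a = mean(ma), mean_b = mean(mb),
       region_means_a = ma, region_means_b = mb)
}
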