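# Per-bp coverage and log2(IP/input) tracks, aggregate profiles, quintile
# grouping, ranked heatmaps, windowed coarse tracks and NDR correlation.

#' Per-base-pair fragment coverage track
#'
#' Value at base b = (weighted) number of fragments whose protected interval
#' contains b; the genome-wide total equals the sum of fragment lengths.
#'
#' @param fs a [fragment_set()] with known chromosome lengths.
#' @return a [genomic_track()] with `"counts/bp"` semantics.
#' @export
coverage_track <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  if (is.null(fs$chrom_lengths)) cf_stop("coverage requires chromosome lengths")
  fr <- fs$fragments
  over <- which(fr$end > fs$chrom_lengths[fr$chrom] | fr$start < 0L)
  if (length(over)) {
    cf_stop("fragment beyond chromosome end: ",
            fr[over[1], paste0(chrom, ":", start, "-", end)])
  }
  values <- lapply(names(fs$chrom_lengths), function(ch) {
    L <- fs$chrom_lengths[[ch]]
    sub <- fr[chrom == ch]
    if (!nrow(sub)) return(numeric(L))
    cov <- IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                             weight = sub$weight, width = L)
    as.numeric(cov)
  })
  names(values) <- names(fs$chrom_lengths)
  genomic_track(values, chrom_lengths = fs$chrom_lengths,
                semantics = "counts/bp")
}

#' log2(IP/input) ratio track
#'
#' Both coverage tracks are first scaled to a common effective depth (their
#' mean genome-wide total), then the per-base value is
#' `log2((ip + pseudocount) / (input + pseudocount))`. Positions with zero
#' raw coverage in both samples are masked.
#'
#' @param ip,input `"counts/bp"` [genomic_track()]s on identical
#'   chromosomes.
#' @param pseudocount pseudocount added to both scaled tracks (> 0; in
#'   post-scaling counts).
#' @return a [genomic_track()] with `"log2-ratio"` semantics.
#' @export
log_ratio_track <- function(ip, input, pseudocount = 0.5) {
  stopifnot(inherits(ip, "genomic_track"), inherits(input, "genomic_track"))
  if (pseudocount <= 0) cf_stop("pseudocount must be > 0")
  if (!identical(ip$chrom_lengths, input$chrom_lengths)) {
    cf_stop("IP and input tracks have mismatched chromosomes")
  }
  tot_ip <- sum(vapply(ip$values, sum, 0, na.rm = TRUE))
  tot_in <- sum(vapply(input$values, sum, 0, na.rm = TRUE))
  if (tot_ip <= 0 || tot_in <= 0) cf_stop("track totals must be positive")
  target <- (tot_ip + tot_in) / 2
  values <- lapply(names(ip$values), function(ch) {
    a <- ip$values[[ch]] * (target / tot_ip)
    b <- input$values[[ch]] * (target / tot_in)
    v <- log2((a + pseudocount) / (b + pseudocount))
    v[ip$values[[ch]] == 0 & input$values[[ch]] == 0] <- NA_real_
    v
  })
  names(values) <- names(ip$values)
  genomic_track(values, chrom_lengths = ip$chrom_lengths,
                semantics = "log2-ratio")
}

# Oriented window of track values around one anchor: offsets -flank..+flank,
# minus-strand anchors read the track right-to-left. Out-of-bounds -> NA.
anchor_window <- function(track, chrom, pos, strand, flank) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(rep(NA_real_, 2 * flank + 1))
  idx <- if (identical(strand, "-")) pos - (-flank:flank) else pos + (-flank:flank)
  out <- rep(NA_real_, 2 * flank + 1)
  ok <- idx >= 0L & idx < length(v)
  out[ok] <- v[idx[ok] + 1L]
  out
}

#' Aggregate (average) signal profile around anchors
#'
#' For each offset in `-flank..+flank`, the mean of the track value at
#' `anchor + offset` over all anchors (read in transcription orientation for
#' minus-strand anchors). Masked and out-of-bounds positions are excluded
#' from both numerator and denominator; offsets where no anchor contributes
#' are `NA`.
#'
#' @param track a 1-bp [genomic_track()].
#' @param anchors anchor table (chrom, pos, strand, id).
#' @param flank window half-width (bp, > 0).
#' @return object of class `profile_result`: `offset`, `mean`, `n_contrib`.
#' @export
aggregate_profile <- function(track, anchors, flank = 1000L) {
  stopifnot(inherits(track, "genomic_track"), flank > 0,
            track$resolution == 1L)
  a <- as_anchor_table(anchors)
  if (!nrow(a)) cf_stop("anchor list is empty")
  width <- 2L * flank + 1L
  sums <- numeric(width)
  ns <- integer(width)
  for (i in seq_len(nrow(a))) {
    w <- anchor_window(track, a$chrom[i], a$pos[i], a$strand[i], flank)
    ok <- !is.na(w)
    sums[ok] <- sums[ok] + w[ok]
    ns <- ns + ok
  }
  structure(list(offset = -flank:flank,
                 mean = ifelse(ns > 0, sums / ns, NA_real_),
                 n_contrib = ns, n_anchors = nrow(a)),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf("<profile_result> offsets %d..%d over %d anchors\n",
              min(x$offset), max(x$offset), x$n_anchors))
  invisible(x)
}

# mean window signal per anchor (strand-oriented), NaN if all masked
anchor_mean_signal <- function(track, a, flank) {
  vapply(seq_len(nrow(a)), function(i) {
    w <- anchor_window(track, a$chrom[i], a$pos[i], a$strand[i], flank)
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Quintile aggregate profiles
#'
#' Anchors are ranked by mean track signal over their window (descending);
#' split into `n_groups` near-equal groups, sizes differing by at most one
#' with remainders assigned to the top groups and ties broken by anchor id
#' order. Group 1 holds the highest-signal anchors.
#'
#' @inheritParams aggregate_profile
#' @param n_groups number of groups (default 5).
#' @return list of `profile_result` (named Q1..Qn, Q1 = highest signal) with
#'   attribute `membership` (data.table: id, rank score, group).
#' @export
quintile_profiles <- function(track, anchors, flank = 1000L, n_groups = 5L) {
  a <- as_anchor_table(anchors)
  if (nrow(a) < n_groups) {
    cf_stop("need at least ", n_groups, " anchors for ", n_groups, " groups")
  }
  score <- anchor_mean_signal(track, a, flank)
  ord <- order(-score, a$id, na.last = TRUE)
  n <- nrow(a)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  r <- n %% n_groups
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  group <- rep(seq_len(n_groups), times = sizes)
  membership <- data.table::data.table(
    id = a$id[ord], score = score[ord], group = group)
  profiles <- lapply(seq_len(n_groups), function(g) {
    aggregate_profile(track, a[ord[group == g]], flank)
  })
  names(profiles) <- paste0("Q", seq_len(n_groups))
  attr(profiles, "membership") <- membership
  profiles
}

#' Ranked heatmap matrix of signal around anchors
#'
#' One row per anchor (`+/- flank` bp, minus-strand rows flipped so the
#' direction of transcription points right), ordered descending by the named
#' metric; ties broken by anchor id.
#'
#' @inheritParams aggregate_profile
#' @param metrics metric table with a `gene_id` column matching anchor ids.
#' @param metric_name metric column to rank by, or `"self"` to rank by the
#'   row's own mean window signal.
#' @return object of class `heatmap_matrix`: `matrix` (rows in rank order),
#'   `row_ids`, `offset`, `metric_name`, `metric_values`.
#' @export
heatmap_matrix <- function(track, anchors, flank = 1000L, metrics = NULL,
                           metric_name = "self") {
  a <- as_anchor_table(anchors)
  if (!nrow(a)) cf_stop("anchor list is empty")
  if (metric_name == "self") {
    mv <- anchor_mean_signal(track, a, flank)
  } else {
    if (is.null(metrics)) cf_stop("metric table required for metric '", metric_name, "'")
    mt <- data.table::as.data.table(metrics)
    if (!metric_name %in% names(mt)) cf_stop("metric '", metric_name, "' not in table")
    missing <- setdiff(a$id, mt$gene_id)
    if (length(missing)) {
      cf_stop("anchors missing from metric table: ",
              paste(head(missing, 10), collapse = ", "))
    }
    mv <- mt[[metric_name]][match(a$id, mt$gene_id)]
  }
  ord <- order(-mv, a$id, na.last = TRUE)
  rows <- t(vapply(ord, function(i) {
    anchor_window(track, a$chrom[i], a$pos[i], a$strand[i], flank)
  }, numeric(2L * flank + 1L)))
  structure(list(matrix = rows, row_ids = a$id[ord], offset = -flank:flank,
                 metric_name = metric_name, metric_values = mv[ord]),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d rows x %d offsets, ranked by %s (descending)\n",
              nrow(x$matrix), ncol(x$matrix), x$metric_name))
  invisible(x)
}

#' Coarsen a track into fixed windows
#'
#' Non-overlapping tiling from the chromosome start; each window's value is
#' the mean of its unmasked bases (a window with all bases masked is
#' masked). The trailing partial window, if any, is kept.
#'
#' @param track a 1-bp [genomic_track()].
#' @param window window size in bp (>= 1).
#' @return a [genomic_track()] at `window` bp resolution.
#' @export
windowed_track <- function(track, window) {
  stopifnot(inherits(track, "genomic_track"), track$resolution == 1L)
  if (!is_count(window, 1)) cf_stop("window must be a positive integer")
  window <- as.integer(window)
  if (window == 1L) return(track)
  values <- lapply(track$values, function(v) {
    bin <- (seq_along(v) - 1L) %/% window
    ok <- !is.na(v)
    sums <- rowsum(ifelse(ok, v, 0), bin)
    ns <- rowsum(as.numeric(ok), bin)
    out <- as.vector(sums / ns)   # NaN when all-masked
    out[ns == 0] <- NA_real_
    out
  })
  genomic_track(values, chrom_lengths = track$chrom_lengths,
                semantics = track$semantics, resolution = window)
}

#' Remodeler signal versus NDR size correlation
#'
#' For each NDR, the maximum unmasked track value inside the interval;
#' reports the ordinary least-squares R-squared of max signal against NDR
#' width, the diagnostic for whether apparent binding merely tracks the
#' amount of naked DNA.
#'
#' @param track a 1-bp [genomic_track()] (typically log2(IP/input)).
#' @param ndrs interval table (chrom, start, end, optionally name).
#' @return list: `r_squared`, `n`, and per-NDR `table` (name, width_bp,
#'   max_signal).
#' @export
ndr_correlation <- function(track, ndrs) {
  stopifnot(inherits(track, "genomic_track"), track$resolution == 1L)
  nd <- data.table::as.data.table(ndrs)
  if (!"name" %in% names(nd)) nd[, name := as.character(seq_len(.N))]
  res <- lapply(seq_len(nrow(nd)), function(i) {
    v <- track$values[[nd$chrom[i]]]
    if (is.null(v)) return(NULL)
    seg <- v[(nd$start[i] + 1L):nd$end[i]]
    if (all(is.na(seg))) return(NULL)
    data.table::data.table(name = nd$name[i],
                           width_bp = nd$end[i] - nd$start[i],
                           max_signal = max(seg, na.rm = TRUE))
  })
  tab <- data.table::rbindlist(res)
  if (nrow(tab) < 3) cf_stop("need >= 3 NDRs with unmasked signal")
  fit <- stats::lm(max_signal ~ width_bp, data = tab)
  list(r_squared = summary(fit)$r.squared, n = nrow(tab), table = tab)
}
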