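# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (double loops, per-base membership) so they stay
# independent of the vectorized implementation paths they check.

make_fs <- function(starts, ends, chrom = "chr1", chrom_len = NULL,
                    role = "input", weights = 1) {
  fragment_set(
    data.frame(chrom = chrom, start = starts, end = ends, weight = weights),
    chrom_lengths = if (!is.null(chrom_len)) setNames(chrom_len, unique(chrom)[1]),
    role = role)
}

make_track <- function(v, chrom = "chr1", semantics = "metric") {
  genomic_track(setNames(list(v), chrom), semantics = semantics)
}

# tiny in-memory genome for sequence tests
make_genome <- function(seqs) {
  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 features = data.table::data.table(),
                 chrom_lengths = setNames(nchar(seqs), names(seqs))),
            class = "cf_genome")
}

oracle_coverage <- function(starts, ends, L) {
  v <- numeric(L)
  for (i in seq_along(starts)) {
    for (b in (starts[i] + 1):ends[i]) v[b] <- v[b] + 1
  }
  v
}

# naive per-pair V-plot tally under the documented symmetric binning rule
oracle_vplot_counts <- function(fr, anchors, xhw, xb, ymin, ymax) {
  K <- floor(xhw / xb + 0.5)
  mat <- matrix(0, nrow = 2 * K + 1, ncol = ymax - ymin + 1)
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(fr))) {
      if (fr$chrom[j] != anchors$chrom[i]) next
      len <- fr$end[j] - fr$start[j]
      if (len < ymin || len > ymax) next
      m <- fr$start[j] + floor(len / 2)
      d <- m - anchors$pos[i]
      if (anchors$strand[i] == "-") d <- -d
      if (abs(d) > xhw) next
      k <- sign(d) * floor(abs(d) / xb + 0.5)
      mat[k + K + 1, len - ymin + 1] <- mat[k + K + 1, len - ymin + 1] + 1
    }
  }
  mat
}

oracle_profile <- function(values, anchors, flank) {
  offs <- -flank:flank
  means <- ns <- numeric(length(offs))
  for (k in seq_along(offs)) {
    acc <- c()
    for (i in seq_len(nrow(anchors))) {
      p <- if (anchors$strand[i] == "-") anchors$pos[i] - offs[k]
           else anchors$pos[i] + offs[k]
      if (p < 0 || p >= length(values)) next
      x <- values[p + 1]
      if (!is.na(x)) acc <- c(acc, x)
    }
    ns[k] <- length(acc)
    means[k] <- if (length(acc)) mean(acc) else NA_real_
  }
  list(mean = means, n = ns)
}

oracle_windowed <- function(v, w) {
  nb <- ceiling(length(v) / w)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    seg <- v[((b - 1) * w + 1):min(b * w, length(v))]
    out[b] <- if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
  }
  out
}

oracle_bendability <- function(seq, scale, window) {
  L <- nchar(seq)
  h <- (window - 1) / 2
  chars <- strsplit(toupper(seq), "")[[1]]
  raw <- rep(NA_real_, L)
  for (p in 2:(L - 1)) {
    tri <- paste(chars[(p - 1):(p + 1)], collapse = "")
    if (tri %in% names(scale)) raw[p] <- scale[[tri]]
  }
  out <- rep(NA_real_, L)
  for (p in seq_len(L)) {
    if (p - h < 1 || p + h > L) next
    win <- raw[(p - h):(p + h)]
    if (any(!is.na(win))) out[p] <- mean(win, na.rm = TRUE)
  }
  out
}

# closed-form Welch t statistic and two-sided p
welch_closed_form <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(statistic = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# closed-form OLS R^2 from raw sums
r_squared_closed_form <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
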