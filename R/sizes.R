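# Fragment size distributions and nucleosomal / supernucleosomal AUC
# statistics. "Area under the curve" is a discrete sum over 1-bp length
# bins: after unit-area normalization the densities sum to one, so a class
# AUC is simply the summed density over the class's length range.

#' Fragment length distribution, normalized to unit area
#'
#' @param fs a [fragment_set()].
#' @return object of class `size_distribution`: integer `lengths` support
#'   (min..max observed), per-length `density` summing to 1, and the total
#'   fragment weight.
#' @export
length_histogram <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  if (n_fragments(fs) == 0) cf_stop("cannot build a size distribution from an empty fragment set")
  len <- fragment_lengths(fs)
  w <- fs$fragments$weight
  rng <- range(len)
  counts <- vapply(split(w, factor(len, levels = rng[1]:rng[2])), sum, 0)
  total <- sum(w)
  structure(list(lengths = rng[1]:rng[2],
                 density = unname(counts) / total,
                 normalized = TRUE, total = total),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d-%d bp, mode %d bp, %g fragments\n",
              min(x$lengths), max(x$lengths),
              x$lengths[which.max(x$density)], x$total))
  invisible(x)
}

#' Area under the size distribution over a length class
#'
#' Discrete sum of density over lengths in `[lo, hi]` (inclusive). A range
#' entirely outside the distribution's support yields 0 with a note.
#'
#' @param d a [length_histogram()] result.
#' @param lo,hi class bounds in bp (`lo <= hi`).
#' @return the class AUC (fraction in [0,1] for a normalized distribution).
#' @export
class_auc <- function(d, lo, hi) {
  stopifnot(inherits(d, "size_distribution"), lo <= hi)
  sel <- d$lengths >= lo & d$lengths <= hi
  if (!any(sel)) {
    message("class_auc: range [", lo, ",", hi,
            "] lies outside the distribution support; returning 0")
    return(0)
  }
  sum(d$density[sel])
}

#' Supernucleosomal/nucleosomal AUC ratio
#'
#' Default classes follow the conventional nucleosomal (141-250 bp) and
#' supernucleosomal (251-428 bp) fragment-length windows.
#'
#' @param d a [length_histogram()] result.
#' @param nucleosomal,supernucleosomal length ranges `c(lo, hi)` in bp
#'   (must be disjoint).
#' @return list with `nucleosomal_auc`, `supernucleosomal_auc`, `ratio`.
#' @export
supernuc_ratio <- function(d, nucleosomal = c(141L, 250L),
                           supernucleosomal = c(251L, 428L)) {
  if (max(min(nucleosomal), min(supernucleosomal)) <=
      min(max(nucleosomal), max(supernucleosomal))) {
    cf_stop("nucleosomal and supernucleosomal ranges must be disjoint")
  }
  nuc <- class_auc(d, nucleosomal[1], nucleosomal[2])
  sup <- suppressMessages(class_auc(d, supernucleosomal[1], supernucleosomal[2]))
  if (nuc <= 0) cf_stop("nucleosomal AUC is zero; ratio undefined")
  list(nucleosomal_auc = nuc, supernucleosomal_auc = sup, ratio = sup / nuc)
}

#' ChIP/input enrichment ratio-of-ratios
#'
#' The ChIP sample's supernucleosomal/nucleosomal AUC ratio divided by the
#' input sample's, the summary statistic for supernucleosomal enrichment in
#' IP versus input chromatin.
#'
#' @param chip,input [length_histogram()] results for the IP and input
#'   samples.
#' @inheritParams supernuc_ratio
#' @return list with both per-sample ratios and `ratio_of_ratios`.
#' @export
enrichment_ratio <- function(chip, input, nucleosomal = c(141L, 250L),
                             supernucleosomal = c(251L, 428L)) {
  rc <- supernuc_ratio(chip, nucleosomal, supernucleosomal)
  ri <- supernuc_ratio(input, nucleosomal, supernucleosomal)
  if (ri$ratio == 0) cf_stop("input supernucleosomal AUC is zero; ratio-of-ratios undefined")
  list(chip_ratio = rc$ratio, input_ratio = ri$ratio,
       ratio_of_ratios = rc$ratio / ri$ratio)
}

#' Compare two groups of AUC ratios (Welch's t-test)
#'
#' Two-sided Welch two-sample t-test on per-sample ratios (the package's
#' documented choice of test for group comparisons of enrichment ratios).
#'
#' @param group_a,group_b numeric vectors of per-sample ratios (>= 2 each).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
compare_ratio_groups <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    cf_stop("each group needs >= 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    cf_stop("both groups are constant; Welch t-test undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
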