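# Synthetic chromatin simulator: genome sequence with A+T-rich features,
# phased nucleosome arrays around TF-bound NDRs, one-sided remodeler
# protections spanning TFBS-to-nucleosome linkers, and paired-end fragment
# emission under a tunable MNase digestion model. All randomness flows from
# one integer seed through documented per-operation streams.

SIM_STREAMS <- c(genome = 1L, chromatin = 2L, fragments = 3L, metrics = 4L)

#' Specify a synthetic genome
#'
#' @param chrom_lengths named integer chromosome lengths (bp).
#' @param features data.frame of feature placements with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `name`, `class_label`
#'   (e.g. `"TFBS"`, `"NDR"`, `"ORF"`, `"centromere"`,
#'   `"centromere_element"`) and `at_fraction` (A+T fraction to impose on
#'   the feature sequence, `NA` = background composition).
#' @param background_gc background G+C fraction (default 0.38, the
#'   budding-yeast genome average).
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, features = NULL, background_gc = 0.38) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    cf_stop("chrom_lengths must be a named vector")
  }
  if (background_gc < 0 || background_gc > 1) cf_stop("background_gc must be in [0,1]")
  if (is.null(features)) {
    features <- data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), name = character(), class_label = character(),
      at_fraction = numeric())
  }
  ft <- data.table::as.data.table(features)
  for (col in c("strand", "name")) if (!col %in% names(ft)) ft[, (col) := "."]
  if (!"at_fraction" %in% names(ft)) ft[, at_fraction := NA_real_]
  ft <- ft[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), strand = as.character(strand),
               name = as.character(name), class_label = as.character(class_label),
               at_fraction = as.numeric(at_fraction))]
  if (nrow(ft)) {
    if (any(ft$start < 0 | ft$start >= ft$end)) cf_stop("invalid feature interval")
    unknown <- setdiff(unique(ft$chrom), names(chrom_lengths))
    if (length(unknown)) cf_stop("feature chromosome(s) not declared: ",
                                 paste(unknown, collapse = ", "))
    over <- ft$end > chrom_lengths[ft$chrom]
    if (any(over)) cf_stop("feature(s) exceed chromosome bounds: ",
                           paste(ft[over, paste0(chrom, ":", start, "-", end)][1:min(3, sum(over))],
                                 collapse = ", "))
    bad_at <- !is.na(ft$at_fraction) & (ft$at_fraction < 0 | ft$at_fraction > 1)
    if (any(bad_at)) cf_stop("at_fraction must be in [0,1]")
    # same-class features must not overlap one another
    for (cl in unique(ft$class_label)) {
      sub <- ft[class_label == cl][order(chrom, start)]
      if (nrow(sub) > 1) {
        ov <- sub[, chrom == data.table::shift(chrom) &
                    start < data.table::shift(end)][-1]
        if (any(ov)) {
          i <- which(ov)[1] + 1L
          cf_stop("overlapping '", cl, "' features: ",
                  sub$chrom[i - 1], ":", sub$start[i - 1], "-", sub$end[i - 1],
                  " and ", sub$chrom[i], ":", sub$start[i], "-", sub$end[i])
        }
      }
    }
  }
  structure(list(chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths)),
                 features = ft, background_gc = background_gc),
            class = "genome_spec")
}

#' Demonstration genome layout
#'
#' Builds a deterministic feature layout emulating budding-yeast promoter
#' geometry: gene cassettes of a promoter NDR (with a TFBS centered inside)
#' followed by an ORF, strands alternating, plus a tail of A+T-rich
#' centromeres with CDEI/CDEII/CDEIII elements. NDR half-widths cycle
#' through `ndr_half_widths` so NDR size varies independently of anything
#' else.
#'
#' @param n_genes number of gene cassettes.
#' @param n_centromeres number of 200-bp centromeres (0.9 A+T overall).
#' @param orf_length ORF length (bp).
#' @param ndr_half_widths recycled vector of NDR half-widths (bp).
#' @param tfbs_width TFBS width (bp).
#' @param spacer intergenic spacer between cassettes (bp).
#' @param n_sites_per_class number of 100-bp "remodeling site" regions per
#'   composition class (class A at `site_at_fractions[1]` A+T, class B at
#'   `site_at_fractions[2]`), used by the bendability comparison.
#' @param site_at_fractions A+T fractions of the two site classes.
#' @param background_gc background G+C fraction.
#' @return a [genome_spec()] on one chromosome `"chrS"`.
#' @export
demo_genome_spec <- function(n_genes = 500, n_centromeres = 16,
                             orf_length = 1200L,
                             ndr_half_widths = 100L,
                             tfbs_width = 16L, spacer = 400L,
                             n_sites_per_class = 29L,
                             site_at_fractions = c(0.85, 0.50),
                             background_gc = 0.38) {
  stopifnot(is_count(n_genes, 1), n_centromeres >= 0)
  hw <- rep_len(as.integer(ndr_half_widths), n_genes)
  feats <- vector("list", n_genes)
  cursor <- 1000L
  for (i in seq_len(n_genes)) {
    h <- hw[i]
    plus <- i %% 2L == 1L
    if (plus) {
      ndr_start <- cursor
      ndr_end <- ndr_start + 2L * h
      c0 <- ndr_start + h
      orf_start <- ndr_end
      orf_end <- orf_start + orf_length
      strand <- "+"
      cursor <- orf_end + spacer
    } else {
      orf_start <- cursor
      orf_end <- orf_start + orf_length
      ndr_start <- orf_end
      ndr_end <- ndr_start + 2L * h
      c0 <- ndr_start + h
      strand <- "-"
      cursor <- ndr_end + spacer
    }
    feats[[i]] <- data.table::data.table(
      chrom = "chrS",
      start = c(ndr_start, c0 - tfbs_width %/% 2L, orf_start),
      end = c(ndr_end, c0 - tfbs_width %/% 2L + tfbs_width, orf_end),
      strand = c(".", ".", strand),
      name = c(sprintf("NDR%04d", i), sprintf("TFBS%04d", i), sprintf("gene%04d", i)),
      class_label = c("NDR", "TFBS", "ORF"),
      at_fraction = NA_real_)
  }
  cen <- NULL
  if (n_centromeres > 0) {
    cursor <- cursor + 2000L
    cen <- vector("list", n_centromeres)
    for (j in seq_len(n_centromeres)) {
      s <- cursor
      # 200 bp point centromere: CDEI 8 bp, CDEII 160 bp (highly A+T rich),
      # CDEIII 32 bp; element fills average to ~0.90 A+T over the body
      cen[[j]] <- data.table::data.table(
        chrom = "chrS",
        start = c(s, s, s + 8L, s + 168L),
        end = c(s + 200L, s + 8L, s + 168L, s + 200L),
        strand = ".",
        name = c(sprintf("CEN%02d", j), sprintf("CEN%02d_CDEI", j),
                 sprintf("CEN%02d_CDEII", j), sprintf("CEN%02d_CDEIII", j)),
        class_label = c("centromere", rep("centromere_element", 3)),
        at_fraction = c(NA_real_, 0.70, 0.95, 0.70))
      cursor <- cursor + 1200L
    }
  }
  sites <- NULL
  if (n_sites_per_class > 0) {
    cursor <- cursor + 2000L
    mk_sites <- function(k, cls, at) {
      s <- cursor + (seq_len(k) - 1L) * 300L
      data.table::data.table(
        chrom = "chrS", start = s, end = s + 100L, strand = ".",
        name = sprintf("site%s%02d", cls, seq_len(k)),
        class_label = paste0("remodeling_site_", cls), at_fraction = at)
    }
    sa <- mk_sites(n_sites_per_class, "A", site_at_fractions[1])
    cursor <- cursor + n_sites_per_class * 300L + 500L
    sb <- mk_sites(n_sites_per_class, "B", site_at_fractions[2])
    cursor <- cursor + n_sites_per_class * 300L
    sites <- list(sa, sb)
  }
  ft <- data.table::rbindlist(c(feats, cen, sites))
  genome_spec(chrom_lengths = c(chrS = cursor + 1000L), features = ft,
              background_gc = background_gc)
}

sample_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Build a synthetic genome sequence from a spec
#'
#' Background sequence is drawn i.i.d. at the genome_spec's background G+C fraction; features
#' with a declared `at_fraction` have their window redrawn at that A+T
#' fraction (A and T equiprobable, likewise C and G). Deterministic for a
#' given spec and seed.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @return an object of class `cf_genome`: list with `seq` (named
#'   `DNAStringSet`), `features` (data.table) and `chrom_lengths`.
#' @export
build_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  seqs <- with_stream(seed, SIM_STREAMS[["genome"]], {
    out <- lapply(names(spec$chrom_lengths), function(ch) {
      chars <- sample_dna(spec$chrom_lengths[[ch]], spec$background_gc)
      ft <- spec$features[chrom == ch & !is.na(at_fraction)]
      if (nrow(ft)) {
        for (i in seq_len(nrow(ft))) {
          w <- ft$end[i] - ft$start[i]
          at <- ft$at_fraction[i]
          p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
          chars[(ft$start[i] + 1L):ft$end[i]] <-
            sample(names(p), w, replace = TRUE, prob = p)
        }
      }
      paste(chars, collapse = "")
    })
    names(out) <- names(spec$chrom_lengths)
    out
  })
  structure(list(seq = Biostrings::DNAStringSet(unlist(seqs)),
                 features = data.table::copy(spec$features),
                 chrom_lengths = spec$chrom_lengths),
            class = "cf_genome")
}

#' @export
print.cf_genome <- function(x, ...) {
  cat(sprintf("<cf_genome> %d chromosome(s), %.3g Mb, %d feature(s)\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(x$features)))
  invisible(x)
}

#' Place nucleosomes and protection units on a genome
#'
#' Nucleosome-depleted regions (NDRs) are taken from the genome's declared
#' `NDR` features; any TFBS not inside a declared NDR gets one of
#' `2 * ndr_half_width` bp centered on it. Dyads tile every inter-NDR span at
#' the stated repeat length with the first core edge abutting the span start,
#' so flanking nucleosomes abut NDR boundaries. Each TFBS also yields two
#' candidate one-sided remodeler protections spanning from the flanking
#' nucleosome core, across the intervening linker, to the far edge of the
#' TFBS (left and right versions), modelling dynamic protection of linker
#' DNA on one or the other side of the factor.
#'
#' @param genome a `cf_genome` (or a [genome_spec()], sequence not needed).
#' @param repeat_length nucleosomal repeat length (bp, >= core; default 165,
#'   the budding-yeast average, giving 165 - 147 = 18 bp linkers).
#' @param core core particle length (bp, default 147).
#' @param ndr_half_width default NDR half-width for TFBSs lacking a declared
#'   NDR (bp).
#' @param footprint_pad padding of the TF footprint beyond the TFBS (bp).
#' @param occupancy occupancy probability of each one-sided remodeler
#'   protection, in [0,1].
#' @param seed integer seed (reserved; placement is fully deterministic).
#' @return an object of class `chromatin_state`.
#' @export
place_chromatin <- function(genome, repeat_length = 165L, core = 147L,
                            ndr_half_width = 100L, footprint_pad = 5L,
                            occupancy = 0.5, seed = 1L) {
  if (repeat_length < core) {
    cf_stop("repeat_length (", repeat_length, ") must be >= core length (",
            core, ")")
  }
  if (occupancy < 0 || occupancy > 1) cf_stop("occupancy must be in [0,1]")
  chrom_lengths <- genome$chrom_lengths
  feats <- genome$features
  half_core_l <- (core - 1L) %/% 2L     # 73 for core 147
  half_core_r <- core - half_core_l     # 74: core = [dyad-73, dyad+74)

  ndrs <- feats[class_label == "NDR", .(chrom, start, end, name)]
  tfbs <- feats[class_label == "TFBS", .(chrom, start, end, name)]
  if (nrow(tfbs)) {
    mid <- interval_midpoint(tfbs$start, tfbs$end)
    covered <- vapply(seq_len(nrow(tfbs)), function(i) {
      nrow(ndrs[chrom == tfbs$chrom[i] & start <= mid[i] & end > mid[i]]) > 0
    }, logical(1))
    if (any(!covered)) {
      add <- tfbs[!covered]
      addmid <- interval_midpoint(add$start, add$end)
      ndrs <- rbind(ndrs, data.table::data.table(
        chrom = add$chrom,
        start = pmax(0L, addmid - as.integer(ndr_half_width)),
        end = pmin(chrom_lengths[add$chrom], addmid + as.integer(ndr_half_width)),
        name = paste0("autoNDR_", add$name)))
    }
  }
  data.table::setorder(ndrs, chrom, start)

  dyads <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    nd <- ndrs[chrom == ch]
    if (nrow(nd) > 1) {  # merge any overlapping NDR intervals
      ir <- IRanges::reduce(IRanges::IRanges(nd$start + 1L, nd$end))
      nd <- data.table::data.table(start = IRanges::start(ir) - 1L,
                                   end = IRanges::end(ir))
    }
    bounds <- c(0L, as.vector(rbind(nd$start, nd$end)), L)
    spans <- matrix(bounds, ncol = 2, byrow = TRUE)
    # arrays are phased off NDR boundaries: the flanking core edge abuts the
    # boundary and successive dyads step inward at the repeat length; a span
    # between two NDRs is phased from both ends (meeting near its middle),
    # and an NDR-free chromosome is tiled from its start
    pos <- unlist(lapply(seq_len(nrow(spans)), function(k) {
      a <- spans[k, 1]; b <- spans[k, 2]
      if (b - a < core) return(integer())
      anchor_left <- k > 1L            # span begins at an NDR end
      anchor_right <- k < nrow(spans)  # span ends at an NDR start
      tile_from_left <- function() {
        first <- a + half_core_l
        n <- 1L + (b - half_core_r - first) %/% repeat_length
        if (n < 1) integer() else first + repeat_length * (seq_len(n) - 1L)
      }
      tile_from_right <- function() {
        first <- b - half_core_r
        n <- 1L + (first - (a + half_core_l)) %/% repeat_length
        if (n < 1) integer() else
          rev(first - repeat_length * (seq_len(n) - 1L))
      }
      if (!anchor_right) return(tile_from_left())
      if (!anchor_left) return(tile_from_right())
      mid <- (a + b) / 2
      left <- tile_from_left(); left <- left[left <= mid]
      right <- tile_from_right(); right <- right[right > mid]
      # enforce the core-length separation where the two phases meet
      while (length(left) && length(right) &&
             min(right) - max(left) < core) {
        left <- head(left, -1L)
      }
      c(left, right)
    }))
    if (!length(pos)) return(NULL)
    data.table::data.table(chrom = ch, pos = as.integer(pos))
  })
  dyads <- data.table::rbindlist(dyads)
  if (nrow(dyads)) dyads[, unit_id := sprintf("nuc%06d", .I)]

  footprints <- NULL
  protections <- NULL
  if (nrow(tfbs)) {
    footprints <- data.table::data.table(
      chrom = tfbs$chrom,
      start = pmax(0L, tfbs$start - as.integer(footprint_pad)),
      end = pmin(chrom_lengths[tfbs$chrom], tfbs$end + as.integer(footprint_pad)),
      unit_id = paste0("fp_", tfbs$name))
    prot <- lapply(seq_len(nrow(tfbs)), function(i) {
      ch <- tfbs$chrom[i]
      dch <- dyads[chrom == ch]$pos
      left_dyads <- dch[dch + half_core_r <= tfbs$start[i]]
      right_dyads <- dch[dch - half_core_l >= tfbs$end[i]]
      rows <- list()
      if (length(left_dyads)) {
        d <- max(left_dyads)
        rows$left <- data.table::data.table(
          chrom = ch, start = d - half_core_l, end = tfbs$end[i],
          side = "left", tfbs_id = tfbs$name[i], occupancy = occupancy)
      }
      if (length(right_dyads)) {
        d <- min(right_dyads)
        rows$right <- data.table::data.table(
          chrom = ch, start = tfbs$start[i], end = d + half_core_r,
          side = "right", tfbs_id = tfbs$name[i], occupancy = occupancy)
      }
      data.table::rbindlist(rows)
    })
    protections <- data.table::rbindlist(prot)
    if (nrow(protections)) {
      protections[, unit_id := sprintf("span_%s_%s", tfbs_id, side)]
    }
  }

  genes <- feats[class_label == "ORF", .(chrom, start, end, strand, name)]

  structure(list(
    dyads = dyads, repeat_length = as.integer(repeat_length),
    core = as.integer(core), ndrs = ndrs,
    tf_footprints = footprints %||% data.table::data.table(),
    protections = protections %||% data.table::data.table(),
    genes = genes, chrom_lengths = chrom_lengths),
    class = "chromatin_state")
}

#' @export
print.chromatin_state <- function(x, ...) {
  cat(sprintf(paste0("<chromatin_state> %d dyads (repeat %d, core %d), ",
                     "%d NDRs, %d TF footprints, %d spanning protections\n"),
              nrow(x$dyads), x$repeat_length, x$core, nrow(x$ndrs),
              nrow(x$tf_footprints), nrow(x$protections)))
  invisible(x)
}

#' MNase digestion model
#'
#' Per-end exponential nibbling: each fragment end is trimmed inward by an
#' independent Exp(scale) draw (floored to whole bp), so the modal emitted
#' length of a protected unit of maximal span L is L - scale and increasing
#' the extent strictly decreases the mean length. The defaults `extent = 13`
#' and `extent = 23` reproduce a nucleosomal peak at ~170 bp (light, "2.5
#' min"-style digestion) and ~160 bp (heavier, "10 min"-style digestion)
#' respectively for a 147-bp core with 18-bp linkers.
#'
#' @param extent digestion extent (dimensionless; larger = more trimming).
#' @param scale per-end trimming scale in bp (defaults to `extent`).
#' @param family trimming distribution family (only `"exponential"`).
#' @param min_length minimum emitted fragment length (bp).
#' @param max_length maximum emitted fragment length (bp).
#' @return an object of class `digestion_model`.
#' @export
digestion_model <- function(extent = 13, scale = extent,
                            family = "exponential",
                            min_length = 25L, max_length = 1000L) {
  family <- match.arg(family)
  if (min_length < 1) cf_stop("min_length must be >= 1")
  if (scale < 0) cf_stop("trimming scale must be >= 0")
  structure(list(extent = extent, scale = scale, family = family,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digestion_model")
}

#' IP enrichment model
#'
#' Sampling weights are per protected unit, by unit class; in IP samples the
#' weight of remodeler-spanning units is additionally multiplied by
#' `supernuc_boost`, which is therefore (to first order) the designed
#' supernucleosomal/nucleosomal AUC ratio-of-ratios between IP and input.
#' `input_span_weight` sets the input chromatin's supernucleosomal baseline,
#' which is a free parameter of the simulation.
#'
#' @param nucleosome_weight,tf_weight,input_span_weight per-unit input
#'   sampling weights for nucleosome cores, TF footprints and
#'   remodeler-spanning protections (all >= 0).
#' @param supernuc_boost multiplicative IP boost of remodeler-spanning units
#'   (>= 0; 1 = null enrichment).
#' @return an object of class `enrichment_model`.
#' @export
enrichment_model <- function(nucleosome_weight = 1, tf_weight = 2,
                             input_span_weight = 1, supernuc_boost = 2.5) {
  w <- c(nucleosome = nucleosome_weight, tf_footprint = tf_weight,
         remodeler_spanning = input_span_weight)
  if (any(w < 0) || supernuc_boost < 0) cf_stop("weights must be >= 0")
  structure(list(class_weights = w, supernuc_boost = supernuc_boost),
            class = "enrichment_model")
}

# Internal: protected-unit table with per-side trimming overhangs.
build_unit_table <- function(state) {
  linker <- state$repeat_length - state$core
  units <- list()
  if (nrow(state$dyads)) {
    hl <- (state$core - 1L) %/% 2L
    hr <- state$core - hl
    units$nuc <- data.table::data.table(
      chrom = state$dyads$chrom,
      start = state$dyads$pos - hl, end = state$dyads$pos + hr,
      ext_l = linker, ext_r = linker,
      class_label = "nucleosome", unit_id = state$dyads$unit_id,
      base_weight = 1)
  }
  if (nrow(state$tf_footprints)) {
    units$fp <- data.table::data.table(
      chrom = state$tf_footprints$chrom,
      start = state$tf_footprints$start, end = state$tf_footprints$end,
      ext_l = 10L, ext_r = 10L,
      class_label = "tf_footprint", unit_id = state$tf_footprints$unit_id,
      base_weight = 1)
  }
  if (nrow(state$protections)) {
    p <- state$protections
    units$span <- data.table::data.table(
      chrom = p$chrom, start = p$start, end = p$end,
      ext_l = ifelse(p$side == "left", linker, 10L),
      ext_r = ifelse(p$side == "left", 10L, linker),
      class_label = "remodeler_spanning", unit_id = p$unit_id,
      base_weight = p$occupancy)
  }
  ut <- data.table::rbindlist(units)
  # clamp extended span inside the chromosome
  ut[, `:=`(ext_l = pmin(ext_l, start),
            ext_r = pmin(ext_r, state$chrom_lengths[chrom] - end))]
  ut
}

#' Emit paired-end fragments from a chromatin state
#'
#' Each emitted fragment derives from one protected unit (nucleosome core,
#' TF footprint, or one-sided remodeler-spanning protection), extended by
#' its per-side overhang and trimmed at each end by the digestion model.
#' Units are drawn with replacement proportional to the enrichment model's
#' class weights; in `"IP"` samples, remodeler-spanning units are boosted
#' by `supernuc_boost`, and per-gene enrichment scores (if given) modulate
#' the weight of every unit within +/- `gene_window` of a gene 5' end by
#' `2^(gene_strength * score)`.
#'
#' @param state a `chromatin_state`.
#' @param digestion a [digestion_model()].
#' @param enrichment an [enrichment_model()].
#' @param n number of fragments to emit (> 0).
#' @param sample_role `"IP"` or `"input"`.
#' @param seed integer seed.
#' @param gene_enrichment optional data.frame (`gene_id`, `score`) of
#'   designed per-gene IP enrichment scores (applied in IP samples only).
#' @param gene_strength log2-scale strength of per-gene modulation.
#' @param gene_window promoter window half-width around the gene 5' end (bp).
#' @param name sample name.
#' @return a [fragment_set()]; the ground-truth sidecar table (fragment
#'   provenance: source unit, class, extended source interval) is attached
#'   and retrievable with [fragment_provenance()].
#' @export
emit_fragments <- function(state, digestion, enrichment, n,
                           sample_role = c("input", "IP"), seed = 1L,
                           gene_enrichment = NULL, gene_strength = 1,
                           gene_window = 1000L,
                           name = paste0("sim_", sample_role)) {
  sample_role <- match.arg(sample_role)
  stopifnot(inherits(state, "chromatin_state"),
            inherits(digestion, "digestion_model"),
            inherits(enrichment, "enrichment_model"))
  if (!is_count(n, 1)) cf_stop("n must be a positive integer")
  ut <- build_unit_table(state)
  if (!nrow(ut)) cf_stop("chromatin state has no protected units")
  w <- enrichment$class_weights[ut$class_label] * ut$base_weight
  if (sample_role == "IP") {
    w[ut$class_label == "remodeler_spanning"] <-
      w[ut$class_label == "remodeler_spanning"] * enrichment$supernuc_boost
    if (!is.null(gene_enrichment) && nrow(state$genes)) {
      ge <- data.table::as.data.table(gene_enrichment)
      stopifnot(all(c("gene_id", "score") %in% names(ge)))
      g <- merge(state$genes, ge, by.x = "name", by.y = "gene_id")
      if (nrow(g)) {
        class_tot <- tapply(w, ut$class_label, sum)
        a5 <- ifelse(g$strand == "+", g$start, g$end - 1L)
        umid <- interval_midpoint(ut$start, ut$end)
        for (k in seq_len(nrow(g))) {
          hit <- ut$chrom == g$chrom[k] &
            abs(umid - a5[k]) <= gene_window
          w[hit] <- w[hit] * 2^(gene_strength * g$score[k])
        }
        # gene modulation redistributes weight within each unit class but
        # leaves the class mix (hence the designed supernucleosomal boost)
        # unchanged
        resc <- class_tot / tapply(w, ut$class_label, sum)
        w <- w * resc[ut$class_label]
      }
    }
  }
  if (all(w == 0)) cf_stop("all unit sampling weights are zero")

  out <- with_stream(seed, SIM_STREAMS[["fragments"]], {
    idx <- sample.int(nrow(ut), n, replace = TRUE, prob = w)
    s0 <- ut$start[idx] - ut$ext_l[idx]
    e0 <- ut$end[idx] + ut$ext_r[idx]
    draw_trim <- function(m) {
      if (digestion$scale == 0) rep(0L, m) else
        as.integer(floor(rexp(m, rate = 1 / digestion$scale)))
    }
    s <- s0 + draw_trim(n)
    e <- e0 - draw_trim(n)
    for (round in 1:50) {
      bad <- which(e - s < digestion$min_length | e - s > digestion$max_length)
      if (!length(bad)) break
      s[bad] <- s0[bad] + draw_trim(length(bad))
      e[bad] <- e0[bad] - draw_trim(length(bad))
    }
    bad <- which(e - s < digestion$min_length | e - s > digestion$max_length)
    if (length(bad)) { s[bad] <- s0[bad]; e[bad] <- e0[bad] }
    list(idx = idx, s = s, e = e, s0 = s0, e0 = e0)
  })

  fs <- fragment_set(
    data.table::data.table(chrom = ut$chrom[out$idx], start = out$s, end = out$e),
    chrom_lengths = state$chrom_lengths, name = name,
    role = if (sample_role == "IP") "IP" else "input",
    digestion = sprintf("extent%g", digestion$extent))
  attr(fs, "provenance") <- data.table::data.table(
    fragment = seq_len(n),
    unit_id = ut$unit_id[out$idx],
    class_label = ut$class_label[out$idx],
    source_start = out$s0, source_end = out$e0)
  fs
}

#' Ground-truth provenance of simulated fragments
#' @param fs a simulated [fragment_set()]
#' @return sidecar data.table: fragment index, source unit id and class, and
#'   the extended source interval containing the fragment
#' @export
fragment_provenance <- function(fs) {
  p <- attr(fs, "provenance")
  if (is.null(p)) cf_stop("fragment set carries no provenance sidecar")
  p
}

#' Simulate per-gene metrics coupled to designed IP enrichment
#'
#' Draws a designed per-gene enrichment score (standard normal, log2-scale)
#' and three gene metrics -- `expression` (log2 arbitrary units), `turnover`
#' (log2 turnover ratio) and `txn_rate` (mRNA/hr) -- each as a linear
#' transform of `coupling * score + sqrt(1 - coupling^2) * noise`, so the
#' realized Pearson correlation between each metric and the designed
#' enrichment equals `coupling` up to sampling error.
#'
#' @param genome a `cf_genome` or [genome_spec()] whose `ORF` features
#'   define the gene set (>= 10 genes required).
#' @param coupling target Pearson correlation in [-1, 1].
#' @param seed integer seed.
#' @return data.table: gene_id, expression, turnover, txn_rate,
#'   designed_enrichment.
#' @export
simulate_gene_metrics <- function(genome, coupling = 0.8, seed = 1L) {
  if (abs(coupling) > 1) cf_stop("|coupling| must be <= 1")
  genes <- genome$features[class_label == "ORF"]
  ng <- nrow(genes)
  if (ng < 10) cf_stop("need >= 10 genes for meaningful correlations (got ",
                       ng, ")")
  with_stream(seed, SIM_STREAMS[["metrics"]], {
    z <- rnorm(ng)
    couple <- function() coupling * z + sqrt(1 - coupling^2) * rnorm(ng)
    data.table::data.table(
      gene_id = genes$name,
      expression = 8 + 2 * couple(),
      turnover = 0.5 + 0.8 * couple(),
      txn_rate = pmax(0.1, 30 + 8 * couple()),
      designed_enrichment = z)
  })
}
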