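# Simulator: genome construction, chromatin placement, fragment emission,
# gene metrics -- with ground-truth recovery checks.

one_cen_spec <- function(at = 0.9) {
  genome_spec(
    c(chrT = 1000L),
    data.frame(chrom = "chrT", start = 400L, end = 600L, strand = ".",
               name = "CEN1", class_label = "centromere", at_fraction = at))
}

# nucleosome-only state with NDR buffers at both chromosome ends so no
# protected unit is clamped by a chromosome edge
buffered_nuc_state <- function(L = 2000L, repeat_length = 165L) {
  spec <- genome_spec(
    c(chrN = L),
    data.frame(chrom = "chrN", start = c(0L, L - 100L), end = c(100L, L),
               strand = ".", name = c("edgeL", "edgeR"), class_label = "NDR",
               at_fraction = NA_real_))
  place_chromatin(build_genome(spec, seed = 5), repeat_length = repeat_length)
}

test_that("feature windows acquire the requested A+T fraction", {
  g <- build_genome(one_cen_spec(0.9), seed = 7)
  win <- Biostrings::subseq(g$seq[["chrT"]], 401, 600)
  at <- sum(Biostrings::letterFrequency(win, c("A", "T"))) / 200
  expect_gte(at, 0.85)
  expect_lte(at, 0.95)
  # background stays near the declared background G+C
  gc_all <- sum(Biostrings::letterFrequency(g$seq[["chrT"]], c("G", "C"))) / 1000
  expect_lt(abs(gc_all - (0.38 * 0.8 + 0.1 * 0.2)), 0.08)
})

test_that("featureless specs give exact-length sequences and empty annotations", {
  spec <- genome_spec(c(a = 500L, b = 321L))
  g <- build_genome(spec, seed = 1)
  expect_equal(unname(Biostrings::width(g$seq)), c(500L, 321L))
  expect_equal(nrow(g$features), 0L)
})

test_that("genome construction is seed-deterministic", {
  g1 <- build_genome(one_cen_spec(), seed = 42)
  g2 <- build_genome(one_cen_spec(), seed = 42)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  g3 <- build_genome(one_cen_spec(), seed = 43)
  expect_false(identical(as.character(g1$seq), as.character(g3$seq)))
})

test_that("overlapping same-class features are rejected with coordinates", {
  expect_error(
    genome_spec(c(c = 1000L),
                data.frame(chrom = "c", start = c(10L, 50L), end = c(100L, 150L),
                           class_label = "ORF")),
    "overlapping 'ORF'.*c:10-100.*c:50-150")
  # different classes may overlap freely
  expect_silent(
    genome_spec(c(c = 1000L),
                data.frame(chrom = "c", start = c(10L, 50L), end = c(100L, 150L),
                           class_label = c("ORF", "NDR"))))
})

test_that("dyad spacing reproduces repeat-minus-core linker lengths", {
  bare <- build_genome(genome_spec(c(x = 5000L)), seed = 1)
  for (case in list(c(165L, 18L), c(154L, 7L))) {
    st <- place_chromatin(bare, repeat_length = case[1])
    gaps <- diff(st$dyads$pos)
    expect_equal(mean(gaps) - st$core, case[2])
  }
  expect_error(place_chromatin(build_genome(genome_spec(c(x = 2000L)), seed = 1),
                               repeat_length = 140L), "core")
})

test_that("a bare chromosome of length 10x repeat holds exactly 10 evenly spaced dyads", {
  g <- build_genome(genome_spec(c(x = 1650L)), seed = 1)
  st <- place_chromatin(g, repeat_length = 165L)
  expect_equal(nrow(st$dyads), 10L)
  expect_equal(unique(diff(st$dyads$pos)), 165L)
})

test_that("every TFBS is centered in an NDR whose boundaries abut nucleosome cores", {
  spec <- demo_genome_spec(n_genes = 10, n_centromeres = 0, n_sites_per_class = 0)
  g <- build_genome(spec, seed = 3)
  st <- place_chromatin(g)
  tf <- g$features[g$features$class_label == "TFBS", ]
  mids <- tf$start + (tf$end - tf$start) %/% 2L
  for (i in seq_along(mids)) {
    nd <- st$ndrs[st$ndrs$start <= mids[i] & st$ndrs$end > mids[i], ]
    expect_equal(nrow(nd), 1L)
    # TFBS midpoint sits at the NDR center
    expect_lte(abs((nd$start + (nd$end - nd$start) / 2) - mids[i]), 1)
    # NDR contains no dyads; first dyads outside abut the boundaries
    expect_equal(sum(st$dyads$pos > nd$start & st$dyads$pos < nd$end), 0L)
    left <- max(st$dyads$pos[st$dyads$pos < nd$start])
    right <- min(st$dyads$pos[st$dyads$pos > nd$end])
    expect_equal(left + (st$core - (st$core - 1L) %/% 2L), nd$start)
    expect_equal(right - (st$core - 1L) %/% 2L, nd$end)
  }
})

test_that("zero-scale digestion emits exact core-plus-overhang lengths", {
  st <- buffered_nuc_state()
  fs <- emit_fragments(st, digestion_model(extent = 0), enrichment_model(),
                       n = 500, sample_role = "input", seed = 1)
  # core 147 + full 18 bp linker overhang on each side
  expect_true(all(fragment_lengths(fs) == 147L + 2L * 18L))
})

test_that("every fragment is contained in its source protection (conservation)", {
  spec <- demo_genome_spec(n_genes = 12, n_centromeres = 0, n_sites_per_class = 0)
  st <- place_chromatin(build_genome(spec, seed = 2))
  fs <- emit_fragments(st, digestion_model(extent = 13), enrichment_model(),
                       n = 5000, sample_role = "IP", seed = 9)
  prov <- fragment_provenance(fs)
  expect_equal(nrow(prov), 5000L)
  expect_true(all(fs$fragments$start >= prov$source_start))
  expect_true(all(fs$fragments$end <= prov$source_end))
  expect_true(all(prov$class_label %in%
                  c("nucleosome", "tf_footprint", "remodeler_spanning")))
})

test_that("emission is seed-deterministic and respects length bounds", {
  st <- buffered_nuc_state()
  dig <- digestion_model(extent = 30, min_length = 25, max_length = 180)
  f1 <- emit_fragments(st, dig, enrichment_model(), n = 2000,
                       sample_role = "input", seed = 77)
  f2 <- emit_fragments(st, dig, enrichment_model(), n = 2000,
                       sample_role = "input", seed = 77)
  expect_identical(f1$fragments, f2$fragments)
  expect_true(all(fragment_lengths(f1) >= 25L & fragment_lengths(f1) <= 180L))
})

test_that("null enrichment leaves IP and input size distributions indistinguishable", {
  # smoke check at a fixed seed, as documented -- not a universal guarantee
  spec <- demo_genome_spec(n_genes = 20, n_centromeres = 0, n_sites_per_class = 0)
  st <- place_chromatin(build_genome(spec, seed = 4))
  enr0 <- enrichment_model(supernuc_boost = 1)
  dig <- digestion_model(extent = 13)
  ip <- emit_fragments(st, dig, enr0, n = 10000, sample_role = "IP", seed = 100)
  input <- emit_fragments(st, dig, enr0, n = 10000, sample_role = "input", seed = 101)
  ks <- suppressWarnings(stats::ks.test(fragment_lengths(ip),
                                        fragment_lengths(input)))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero spanning weight equalizes IP and input supernucleosomal fractions", {
  spec <- demo_genome_spec(n_genes = 20, n_centromeres = 0, n_sites_per_class = 0)
  st <- place_chromatin(build_genome(spec, seed = 4))
  enr <- enrichment_model(input_span_weight = 0, supernuc_boost = 5)
  dig <- digestion_model(extent = 13)
  sup_frac <- function(fs) mean(fragment_lengths(fs) >= 251)
  ip <- emit_fragments(st, dig, enr, n = 10000, sample_role = "IP", seed = 8)
  input <- emit_fragments(st, dig, enr, n = 10000, sample_role = "input", seed = 9)
  expect_lt(abs(sup_frac(ip) - sup_frac(input)), 0.01)
})

test_that("increasing digestion extent strictly decreases mean fragment length", {
  st <- buffered_nuc_state(L = 5000L)
  means <- vapply(c(2, 8, 13, 23, 35), function(ext) {
    fs <- emit_fragments(st, digestion_model(extent = ext), enrichment_model(),
                         n = 8000, sample_role = "input", seed = 55)
    mean(fragment_lengths(fs))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("gene metrics realize the designed enrichment coupling", {
  spec <- demo_genome_spec(n_genes = 1000, n_centromeres = 0,
                           n_sites_per_class = 0)
  m0 <- simulate_gene_metrics(spec, coupling = 0, seed = 21)
  for (col in c("expression", "turnover", "txn_rate")) {
    expect_lt(abs(cor(m0[[col]], m0$designed_enrichment)), 0.1)
  }
  m8 <- simulate_gene_metrics(spec, coupling = 0.8, seed = 21)
  for (col in c("expression", "turnover", "txn_rate")) {
    r <- cor(m8[[col]], m8$designed_enrichment)
    expect_gte(r, 0.7)
    expect_lte(r, 0.9)
  }
  expect_identical(m8, simulate_gene_metrics(spec, coupling = 0.8, seed = 21))
  expect_error(simulate_gene_metrics(spec, coupling = 1.2), "coupling")
  tiny <- demo_genome_spec(n_genes = 5, n_centromeres = 0, n_sites_per_class = 0)
  expect_error(simulate_gene_metrics(tiny, 0.5, 1), ">= 10 genes")
})
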