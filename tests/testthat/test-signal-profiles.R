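anchors_at <- function(pos, strand = "+", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = strand,
             id = as.character(seq_along(pos)))
}

test_that("coverage counts per-base fragment membership and conserves length totals", {
  fs <- make_fs(100, 200, chrom_len = 300)
  tr <- coverage_track(fs)
  expect_equal(tr$values$chr1[101:200], rep(1, 100))
  expect_equal(sum(tr$values$chr1), 100)
  fs2 <- make_fs(c(100, 150), c(160, 210), chrom_len = 300)
  tr2 <- coverage_track(fs2)
  expect_equal(tr2$values$chr1[151:160], rep(2, 10))
  # random instance against the naive per-base loop; total = sum of lengths
  withr::with_seed(41, {
    starts <- sample.int(900, 500, replace = TRUE)
    lens <- sample(20:90, 500, replace = TRUE)
  })
  fs3 <- make_fs(starts, starts + lens, chrom_len = 1000)
  tr3 <- coverage_track(fs3)
  expect_equal(tr3$values$chr1, oracle_coverage(starts, starts + lens, 1000))
  expect_equal(sum(tr3$values$chr1), sum(lens))
  expect_error(coverage_track(make_fs(250, 350, chrom_len = 300)),
               "beyond chromosome end")
})

test_that("log-ratio tracks depth-normalize, apply the pseudocount, and mask double zeros", {
  a <- make_track(c(3, 1, 0, 0), semantics = "counts/bp")
  b <- make_track(c(1, 3, 0, 0), semantics = "counts/bp")
  lr <- log_ratio_track(a, b, pseudocount = 0.5)
  expect_equal(lr$values$chr1[1], log2(3.5 / 1.5))
  expect_equal(lr$values$chr1[2], log2(1.5 / 3.5))
  expect_true(all(is.na(lr$values$chr1[3:4])))
  # identical tracks -> 0 everywhere unmasked
  lr0 <- log_ratio_track(a, a)
  expect_equal(lr0$values$chr1[1:2], c(0, 0))
  # a uniform 2x depth difference vanishes after scaling
  c2 <- make_track(c(2, 4, 6, 8), semantics = "counts/bp")
  c1 <- make_track(c(1, 2, 3, 4), semantics = "counts/bp")
  expect_equal(log_ratio_track(c2, c1)$values$chr1, rep(0, 4))
  d <- genomic_track(list(chr2 = c(1, 2)), semantics = "counts/bp")
  expect_error(log_ratio_track(a, d), "mismatched")
})

test_that("aggregate profiles average strand-oriented windows, excluding masked bases", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  tr <- make_track(v)
  # single anchor: profile equals the track slice
  pr <- aggregate_profile(tr, anchors_at(4), flank = 2)
  expect_equal(pr$mean, v[3:7])
  # constant track: profile is that constant regardless of anchors
  prc <- aggregate_profile(make_track(rep(3.5, 50)), anchors_at(c(10, 30)),
                           flank = 5)
  expect_equal(unique(prc$mean), 3.5)
  # random track + mixed strands + mask vs brute-force loop
  withr::with_seed(43, {
    vals <- rnorm(500)
    vals[sample.int(500, 60)] <- NA
    apos <- sample(0:499, 10)
    astr <- sample(c("+", "-"), 10, replace = TRUE)
  })
  trr <- make_track(vals)
  an <- anchors_at(apos, astr)
  got <- aggregate_profile(trr, an, flank = 30)
  ref <- oracle_profile(vals, an, 30)
  expect_equal(got$mean, ref$mean)
  expect_equal(got$n_contrib, ref$n)
})

test_that("quintile grouping follows the remainder and tie rules", {
  tr <- make_track(seq_len(100))
  qp10 <- quintile_profiles(tr, anchors_at(seq(5, 95, by = 10)), flank = 2)
  sizes10 <- table(attr(qp10, "membership")$group)
  expect_equal(unname(as.vector(sizes10)), rep(2L, 5))
  a12 <- anchors_at(seq(4, 92, by = 8))
  qp12 <- quintile_profiles(tr, a12, flank = 2)
  expect_equal(unname(as.vector(table(attr(qp12, "membership")$group))),
               c(3L, 3L, 2L, 2L, 2L))
  # group Q1 holds the highest-signal anchors
  m <- attr(qp12, "membership")
  expect_true(all(m$score[m$group == 1] >= max(m$score[m$group == 5])))
  # all-equal signal: grouping falls back to id order
  qeq <- quintile_profiles(make_track(rep(1, 100)), a12, flank = 2)
  meq <- attr(qeq, "membership")
  expect_equal(meq$id, sort(a12$id))
  expect_error(quintile_profiles(tr, anchors_at(c(10, 20)), flank = 2),
               "at least 5")
})

test_that("heatmaps rank rows by metric descending and flip minus-strand genes", {
  v <- seq(0, 99) / 10
  tr <- make_track(v)
  an <- anchors_at(c(20, 50, 80))
  metrics <- data.frame(gene_id = c("1", "2", "3"), expr = c(5, 1, 9))
  hm <- heatmap_matrix(tr, an, flank = 3, metrics = metrics,
                       metric_name = "expr")
  expect_equal(hm$row_ids, c("3", "1", "2"))
  expect_equal(hm$metric_values, c(9, 5, 1))
  # minus-strand row equals the reversed plus-strand slice
  hneg <- heatmap_matrix(tr, anchors_at(50, strand = "-"), flank = 3)
  hpos <- heatmap_matrix(tr, anchors_at(50, strand = "+"), flank = 3)
  expect_equal(hneg$matrix[1, ], rev(hpos$matrix[1, ]))
  # ranking by "self" signal reproduces the quintile ordering
  an10 <- anchors_at(seq(5, 95, by = 10))
  hm_self <- heatmap_matrix(tr, an10, flank = 2, metric_name = "self")
  qp <- quintile_profiles(tr, an10, flank = 2)
  expect_equal(hm_self$row_ids, attr(qp, "membership")$id)
  expect_error(
    heatmap_matrix(tr, an, flank = 3,
                   metrics = data.frame(gene_id = "1", expr = 1),
                   metric_name = "expr"),
    "missing from metric table: 2, 3")
})

test_that("heatmap column means equal the aggregate profile", {
  withr::with_seed(47, {
    vals <- rnorm(400)
    apos <- sample(50:349, 12)
    astr <- sample(c("+", "-"), 12, replace = TRUE)
  })
  tr <- make_track(vals)
  an <- anchors_at(apos, astr)
  hm <- heatmap_matrix(tr, an, flank = 20, metric_name = "self")
  pr <- aggregate_profile(tr, an, flank = 20)
  expect_equal(unname(colMeans(hm$matrix)), pr$mean)
})

test_that("windowed tracks are block means with mask-aware semantics", {
  cw <- windowed_track(make_track(rep(2.5, 120)), 40)
  expect_equal(cw$values$chr1, rep(2.5, 3))
  expect_equal(cw$resolution, 40L)
  tr <- make_track(c(1, 2, 3))
  expect_identical(windowed_track(tr, 1), tr)
  withr::with_seed(53, {
    v <- rnorm(230)
    v[sample.int(230, 50)] <- NA
  })
  v[41:80] <- NA  # one fully masked window
  got <- windowed_track(make_track(v), 40)
  expect_equal(got$values$chr1, oracle_windowed(v, 40))
  expect_true(is.na(got$values$chr1[2]))
})

test_that("NDR correlation reports OLS R-squared of max signal vs width", {
  # max signal exactly proportional to width -> R^2 = 1
  v <- numeric(2000)
  ndrs <- data.frame(chrom = "chr1", start = c(0, 500, 1000),
                     end = c(100, 700, 1300))
  for (i in 1:3) v[ndrs$end[i]] <- (ndrs$end[i] - ndrs$start[i]) / 100
  nc <- suppressWarnings(ndr_correlation(make_track(v), ndrs))
  expect_equal(nc$r_squared, 1)
  # 3 arbitrary points match the closed form
  v2 <- numeric(2000)
  v2[c(50, 600, 1100)] <- c(1.7, 0.4, 2.2)
  nc2 <- ndr_correlation(make_track(v2), ndrs)
  expect_equal(nc2$r_squared,
               r_squared_closed_form(nc2$table$width_bp, nc2$table$max_signal))
  expect_error(ndr_correlation(make_track(rep(NA_real_, 2000)), ndrs),
               ">= 3 NDRs")
})

test_that("signal designed independent of NDR width yields near-zero R-squared", {
  # one signal peak per NDR, drawn independently of the NDR's width
  withr::with_seed(59, {
    n <- 500
    widths <- sample(60:280, n, replace = TRUE)
    starts <- cumsum(c(10, widths[-n] + 50))
    peaks <- abs(rnorm(n))
  })
  v <- numeric(max(starts + widths) + 100)
  v[starts + widths %/% 2] <- peaks
  ndrs <- data.frame(chrom = "chr1", start = starts, end = starts + widths)
  nc <- ndr_correlation(make_track(v), ndrs)
  expect_equal(nc$n, 500)
  expect_lt(nc$r_squared, 0.05)
})

test_that("genes designed as enriched show stronger promoter log-ratio signal", {
  # end-to-end: coupling 0.8 between designed IP enrichment and expression;
  # the top-expression tertile must beat the bottom tertile over 5' windows
  spec <- demo_genome_spec(n_genes = 99, n_centromeres = 0,
                           n_sites_per_class = 0)
  g <- build_genome(spec, seed = 11)
  st <- place_chromatin(g)
  metrics <- simulate_gene_metrics(g, coupling = 0.8, seed = 11)
  dig <- digestion_model(extent = 13)
  enr <- enrichment_model()
  ip <- emit_fragments(st, dig, enr, n = 60000, sample_role = "IP", seed = 11,
                       gene_enrichment = metrics[, c("gene_id", "designed_enrichment")] |>
                         stats::setNames(c("gene_id", "score")))
  input <- emit_fragments(st, dig, enr, n = 60000, sample_role = "input",
                          seed = 12)
  lr <- log_ratio_track(coverage_track(ip), coverage_track(input))
  anchors <- to_anchors(g$features[g$features$class_label == "ORF", ],
                        "five_prime")
  hm <- heatmap_matrix(lr, anchors, flank = 500, metrics = metrics,
                       metric_name = "expression")
  row_means <- rowMeans(hm$matrix, na.rm = TRUE)
  expect_gt(mean(row_means[1:33]), mean(row_means[67:99]))
})
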