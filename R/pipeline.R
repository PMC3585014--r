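# Config-driven orchestration: one YAML config (simulator-driven or
# file-driven) reproduces every analysis end to end, deterministically for
# a given seed. Every output file records the config hash and seed in a
# header comment.

config_schema <- function() {
  list(
    seed = 1L,
    output_dir = "chromfrag_out",
    data = list(
      simulate = list(
        n_genes = 500L, n_centromeres = 16L,
        ndr_half_widths = c(60L, 80L, 100L, 120L, 140L),
        n_fragments = 200000L,
        digestion_extent = 13,
        supernuc_boost = 2.5,
        input_span_weight = 1,
        coupling = 0.8,
        gene_strength = 1,
        repeat_length = 165L),
      paths = list(
        ip_fragments = NULL, input_fragments = NULL,
        fragment_format = "BED3", genome_fasta = NULL,
        anchors_bed = NULL, gene_anchors_bed = NULL, ndrs_bed = NULL,
        metrics_tsv = NULL, regions_a_bed = NULL, regions_b_bed = NULL)),
    analyses = list(
      sizes = list(enabled = TRUE, nucleosomal = c(141L, 250L),
                   supernucleosomal = c(251L, 428L)),
      vplot = list(enabled = TRUE, x_half_width = 1000L, x_bin = 5L,
                   y_min = 25L, y_max = 424L, y_bin = 1L,
                   anchor_mode = "midpoint"),
      profiles = list(enabled = TRUE, flank = 1000L, n_groups = 5L,
                      pseudocount = 0.5),
      heatmap = list(enabled = TRUE, flank = 1000L, metric = "expression"),
      ndr_correlation = list(enabled = TRUE),
      bendability = list(enabled = TRUE, window = 39L),
      atprofile = list(enabled = TRUE, flank = 200L)))
}

merge_config <- function(schema, user, path = "") {
  if (is.null(user)) return(schema)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown)) {
    cf_stop("unknown config key", if (length(unknown) > 1) "s", ": ",
            paste0(path, unknown, collapse = ", "))
  }
  out <- schema
  for (nm in names(user)) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]]))) {
      out[[nm]] <- merge_config(schema[[nm]], user[[nm]],
                                paste0(path, nm, "."))
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an R list; fills every default, rejects
#' unknown keys (naming them), and enforces that exactly one data source --
#' `data.simulate` or `data.paths` -- is active. Re-validating a
#' materialized config is the identity.
#'
#' @param config YAML file path, list, or `run_config`.
#' @return the materialized configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) cf_stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    unclass(config)
  } else cf_stop("config must be a file path or a list")
  if (inherits(config, "run_config")) {
    # materialized configs fill data for both branches; keep the active one
    user$data <- user$data[user$data_source]
  }
  user$data_source <- NULL
  has_sim <- !is.null(user$data$simulate)
  has_paths <- !is.null(user$data$paths)
  if (has_sim == has_paths) {
    cf_stop("config must set exactly one data source: data.simulate or data.paths")
  }
  cfg <- merge_config(config_schema(), user)
  cfg$data_source <- if (has_sim) "simulate" else "paths"
  if (!is_count(cfg$seed, 0)) cf_stop("seed must be a non-negative integer")
  if (has_paths) {
    p <- cfg$data$paths
    for (key in c("ip_fragments", "input_fragments")) {
      if (is.null(p[[key]])) cf_stop("data.paths.", key, " is required")
    }
    given <- Filter(Negate(is.null),
                    p[setdiff(names(p), "fragment_format")])
    missing <- !vapply(given, file.exists, TRUE)
    if (any(missing)) {
      cf_stop("config references missing file(s): ",
              paste(unlist(given[missing]), collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_stats_json <- function(x, path, header) {
  con <- file(path, "w")
  writeLines(jsonlite::toJSON(c(list(provenance = header), x),
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             con)
  close(con)
}

profile_dt <- function(pr) {
  data.table::data.table(offset = pr$offset,
                         mean = round(pr$mean, 6), n = pr$n_contrib)
}

write_tsv_commented <- function(dt, path, comments) {
  con <- file(path, "w")
  writeLines(paste0("# ", comments), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage on simulated or user-supplied data and
#' writes: per-sample size densities and an AUC/ratio stats JSON, IP and
#' input percent V-plot matrices, aggregate/quintile profile TSVs, a ranked
#' heatmap TSV, an NDR correlation report, a bendability comparison report,
#' a centromeric A+T/PFM table, and a run log. Outputs are deterministic
#' for a given config and seed.
#'
#' @param config a [validate_config()] result, YAML path, or list.
#' @param output_dir optional override of the config's output directory.
#' @return invisibly, a list of stage results plus `output_dir` and
#'   `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  hdr <- sprintf("config_hash=%s seed=%d", hash, as.integer(cfg$seed))
  logf <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("chromfrag %s | R %s",
                         as.character(utils::packageVersion("chromfrag")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 hdr)
  tick <- function(msg, t0) c(log_lines, sprintf("%-24s %.2fs", msg,
                                                 as.numeric(Sys.time()) - t0))
  results <- list()
  seed <- as.integer(cfg$seed)
  an <- cfg$analyses

  run_stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      cf_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    log_lines <<- tick(name, t0)
    res
  }

  # ---- data source -------------------------------------------------------
  if (cfg$data_source == "simulate") {
    sim <- cfg$data$simulate
    inputs <- run_stage("simulate", {
      spec <- demo_genome_spec(n_genes = sim$n_genes,
                               n_centromeres = sim$n_centromeres,
                               ndr_half_widths = sim$ndr_half_widths)
      genome <- build_genome(spec, seed = seed)
      state <- place_chromatin(genome, repeat_length = sim$repeat_length,
                               seed = seed)
      dig <- digestion_model(extent = sim$digestion_extent)
      enr <- enrichment_model(supernuc_boost = sim$supernuc_boost,
                              input_span_weight = sim$input_span_weight)
      metrics <- simulate_gene_metrics(genome, coupling = sim$coupling,
                                       seed = seed)
      ge <- metrics[, .(gene_id, score = designed_enrichment)]
      ip <- emit_fragments(state, dig, enr, n = sim$n_fragments,
                           sample_role = "IP", seed = seed,
                           gene_enrichment = ge,
                           gene_strength = sim$gene_strength)
      input <- emit_fragments(state, dig, enr, n = sim$n_fragments,
                              sample_role = "input", seed = seed + 1L)
      feats <- genome$features
      list(genome = genome, state = state, metrics = metrics,
           ip = ip, input = input,
           tfbs_anchors = to_anchors(feats[class_label == "TFBS"], "midpoint"),
           gene_anchors = to_anchors(feats[class_label == "ORF"], "five_prime"),
           cen_anchors = to_anchors(feats[class_label == "centromere"], "midpoint"),
           ndrs = feats[class_label == "NDR"],
           regions_a = feats[class_label == "remodeling_site_A"],
           regions_b = feats[class_label == "remodeling_site_B"])
    })
  } else {
    p <- cfg$data$paths
    inputs <- run_stage("load", {
      genome <- if (!is.null(p$genome_fasta)) {
        seqs <- read_genome_fasta(p$genome_fasta)
        structure(list(seq = seqs,
                       features = data.table::data.table(),
                       chrom_lengths = setNames(Biostrings::width(seqs),
                                                names(seqs))),
                  class = "cf_genome")
      }
      cl <- if (!is.null(genome)) genome$chrom_lengths
      fmt <- p$fragment_format
      anch <- if (!is.null(p$anchors_bed))
        to_anchors(read_features(p$anchors_bed), cfg$analyses$vplot$anchor_mode)
      ganch <- if (!is.null(p$gene_anchors_bed))
        to_anchors(read_features(p$gene_anchors_bed), "five_prime")
      list(genome = genome,
           ip = read_fragments(p$ip_fragments, fmt, chrom_lengths = cl,
                               role = "IP"),
           input = read_fragments(p$input_fragments, fmt, chrom_lengths = cl,
                                  role = "input"),
           metrics = if (!is.null(p$metrics_tsv)) read_metric_table(p$metrics_tsv),
           tfbs_anchors = anch, gene_anchors = ganch, cen_anchors = anch,
           ndrs = if (!is.null(p$ndrs_bed)) read_features(p$ndrs_bed),
           regions_a = if (!is.null(p$regions_a_bed)) read_features(p$regions_a_bed),
           regions_b = if (!is.null(p$regions_b_bed)) read_features(p$regions_b_bed))
    })
  }

  # ---- sizes -------------------------------------------------------------
  if (isTRUE(an$sizes$enabled)) {
    results$sizes <- run_stage("sizes", {
      d_ip <- length_histogram(inputs$ip)
      d_in <- length_histogram(inputs$input)
      er <- enrichment_ratio(d_ip, d_in,
                             nucleosomal = an$sizes$nucleosomal,
                             supernucleosomal = an$sizes$supernucleosomal)
      dens <- data.table::data.table(
        length = union(d_ip$lengths, d_in$lengths))
      dens[, ip_density := round(d_ip$density[match(length, d_ip$lengths)], 8)]
      dens[, input_density := round(d_in$density[match(length, d_in$lengths)], 8)]
      write_tsv_commented(dens, file.path(out_dir, "size_densities.tsv"), hdr)
      write_stats_json(er, file.path(out_dir, "size_stats.json"), hdr)
      er
    })
  }

  # ---- vplot -------------------------------------------------------------
  if (isTRUE(an$vplot$enabled) && !is.null(inputs$tfbs_anchors)) {
    results$vplot <- run_stage("vplot", {
      vp <- an$vplot
      mk <- function(fs) normalize_vplot(build_vplot(
        fs, inputs$tfbs_anchors, x_half_width = vp$x_half_width,
        x_bin = vp$x_bin, y_min = vp$y_min, y_max = vp$y_max,
        y_bin = vp$y_bin))
      v_ip <- mk(inputs$ip)
      v_in <- mk(inputs$input)
      export_vplot(v_ip, file.path(out_dir, "vplot_ip.tsv"), comments = hdr)
      export_vplot(v_in, file.path(out_dir, "vplot_input.tsv"), comments = hdr)
      list(ip = v_ip, input = v_in)
    })
  }

  # ---- coverage + ratio track (shared by later stages) -------------------
  ratio <- NULL
  if (isTRUE(an$profiles$enabled) || isTRUE(an$heatmap$enabled) ||
      isTRUE(an$ndr_correlation$enabled)) {
    ratio <- run_stage("ratio_track", {
      log_ratio_track(coverage_track(inputs$ip), coverage_track(inputs$input),
                      pseudocount = an$profiles$pseudocount)
    })
    results$ratio_track <- ratio
  }

  # ---- profiles ----------------------------------------------------------
  if (isTRUE(an$profiles$enabled) && !is.null(inputs$gene_anchors)) {
    results$profiles <- run_stage("profiles", {
      pr <- aggregate_profile(ratio, inputs$gene_anchors,
                              flank = an$profiles$flank)
      write_tsv_commented(profile_dt(pr),
                          file.path(out_dir, "profile_orf5.tsv"), hdr)
      qp <- quintile_profiles(ratio, inputs$gene_anchors,
                              flank = an$profiles$flank,
                              n_groups = an$profiles$n_groups)
      qdt <- data.table::data.table(offset = qp[[1]]$offset)
      for (nm in names(qp)) qdt[, (nm) := round(qp[[nm]]$mean, 6)]
      write_tsv_commented(qdt, file.path(out_dir, "profile_quintiles.tsv"), hdr)
      list(aggregate = pr, quintiles = qp)
    })
  }

  # ---- heatmap -----------------------------------------------------------
  if (isTRUE(an$heatmap$enabled) && !is.null(inputs$gene_anchors) &&
      !is.null(inputs$metrics)) {
    results$heatmap <- run_stage("heatmap", {
      hm <- heatmap_matrix(ratio, inputs$gene_anchors,
                           flank = an$heatmap$flank,
                           metrics = inputs$metrics,
                           metric_name = an$heatmap$metric)
      dt <- data.table::as.data.table(round(hm$matrix, 6))
      data.table::setnames(dt, as.character(hm$offset))
      dt <- cbind(data.table::data.table(gene_id = hm$row_ids,
                                         metric = round(hm$metric_values, 6)),
                  dt)
      write_tsv_commented(dt, file.path(out_dir, "heatmap.tsv"), hdr)
      hm
    })
  }

  # ---- NDR correlation ---------------------------------------------------
  if (isTRUE(an$ndr_correlation$enabled) && !is.null(inputs$ndrs) &&
      nrow(inputs$ndrs) >= 3) {
    results$ndr_correlation <- run_stage("ndr_correlation", {
      nc <- ndr_correlation(ratio, inputs$ndrs)
      write_tsv_commented(nc$table[, .(name, width_bp,
                                       max_signal = round(max_signal, 6))],
                          file.path(out_dir, "ndr_table.tsv"), hdr)
      write_stats_json(list(r_squared = nc$r_squared, n = nc$n),
                       file.path(out_dir, "ndr_correlation.json"), hdr)
      nc
    })
  }

  # ---- bendability -------------------------------------------------------
  if (isTRUE(an$bendability$enabled) && !is.null(inputs$genome) &&
      !is.null(inputs$regions_a) && !is.null(inputs$regions_b)) {
    results$bendability <- run_stage("bendability", {
      bc <- compare_region_bendability(inputs$regions_a, inputs$regions_b,
                                       inputs$genome,
                                       window = an$bendability$window)
      write_stats_json(list(mean_difference = bc$mean_difference,
                            p_value = bc$p_value, statistic = bc$statistic,
                            mean_a = bc$mean_a, mean_b = bc$mean_b),
                       file.path(out_dir, "bendability.json"), hdr)
      bc
    })
  }

  # ---- A+T composition profile -------------------------------------------
  if (isTRUE(an$atprofile$enabled) && !is.null(inputs$genome) &&
      !is.null(inputs$cen_anchors) && nrow(inputs$cen_anchors) > 0) {
    results$atprofile <- run_stage("atprofile", {
      p <- pfm_from_anchors(inputs$genome, inputs$cen_anchors,
                            flank = an$atprofile$flank)
      export_pfm(p, file.path(out_dir, "centromere_pfm.tsv"), comments = hdr)
      p
    })
  }

  writeLines(log_lines, logf)
  invisible(c(results, list(output_dir = out_dir, config = cfg,
                            inputs = inputs)))
}
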