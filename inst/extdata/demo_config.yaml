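# chromfrag pipeline configuration template (simulator-driven demo).
# Every key shown is optional except the choice of exactly ONE data source
# (data.simulate or data.paths); omitted keys take the defaults shown here.

seed: 1
output_dir: chromfrag_out

data:
  # --- simulator-driven run ---------------------------------------------
  simulate:
    n_genes: 500              # gene cassettes (promoter NDR + TFBS + ORF)
    n_centromeres: 16         # 200-bp A+T-rich point centromeres
    ndr_half_widths: [60, 80, 100, 120, 140]   # recycled across genes (bp)
    n_fragments: 200000       # fragments per sample (IP and input)
    digestion_extent: 13      # per-end exponential trimming scale (bp);
                              # 13 -> ~170 bp nucleosomal peak, 23 -> ~160 bp
    supernuc_boost: 2.5       # designed IP boost of spanning protections
    input_span_weight: 1      # input chromatin supernucleosomal baseline
    coupling: 0.8             # designed enrichment <-> gene metric correlation
    gene_strength: 1          # log2 strength of per-gene IP modulation
    repeat_length: 165        # nucleosomal repeat (bp; core is 147)
  # --- or: user-supplied files ------------------------------------------
  # paths:
  #   ip_fragments: ip.bed
  #   input_fragments: input.bed
  #   fragment_format: BED3        # or BEDPE
  #   genome_fasta: genome.fa
  #   anchors_bed: tfbs.bed        # BED6 anchor features
  #   gene_anchors_bed: orfs.bed   # BED6 stranded genes (5' anchors)
  #   ndrs_bed: ndrs.bed
  #   metrics_tsv: metrics.tsv     # gene_id + metric columns
  #   regions_a_bed: sitesA.bed    # bendability class A
  #   regions_b_bed: sitesB.bed    # bendability class B

analyses:
  sizes:
    enabled: true
    nucleosomal: [141, 250]        # bp, inclusive
    supernucleosomal: [251, 428]
  vplot:
    enabled: true
    x_half_width: 1000             # bp; 401 x-bins at 5 bp
    x_bin: 5
    y_min: 25                      # 400 1-bp length bins
    y_max: 424
    y_bin: 1
    anchor_mode: midpoint          # midpoint | five_prime | three_prime
  profiles:
    enabled: true
    flank: 1000                    # +/- window around gene 5' ends (bp)
    n_groups: 5                    # quintiles
    pseudocount: 0.5               # post-scaling counts
  heatmap:
    enabled: true
    flank: 1000
    metric: expression             # ranking metric column (or "self")
  ndr_correlation:
    enabled: true
  bendability:
    enabled: true
    window: 39                     # bp, odd
  atprofile:
    enabled: true
    flank: 200                     # 401-bp window centered on centromeres
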