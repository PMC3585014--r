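---
title: "Fragment-centric chromatin analysis with chromfrag: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-centric chromatin analysis with chromfrag: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chromfrag` analyzes paired-end MNase-based chromatin profiling data
(native ChIP-seq of chromatin-bound factors, and the matched input
chromatin) at the level of *protected fragments*: each sequenced pair is
treated as one protein-protected genomic interval, and every analysis is a
function of fragment midpoints, lengths and per-base coverage. The package
implements five analysis families -- fragment size-class statistics,
V-plot matrices, log2(IP/input) signal profiling, sequence composition,
and DNA bendability scoring -- plus a synthetic chromatin simulator that
generates data with known ground truth so that every analysis can be
validated by recovery rather than by eyeballing.

# Coordinate conventions

All internal coordinates are 0-based half-open, matching BED on disk. A
fragment `[start, end)` has length `end - start` and midpoint
`start + floor((end - start) / 2)` (floor tie-break for odd lengths).
Anchor extraction from stranded features follows transcription: the 5'
anchor of a minus-strand gene is `end - 1`, and all window-based analyses
read minus-strand windows right-to-left so that the direction of
transcription points right in profiles and heatmaps.

# Size-class statistics

Fragment length distributions are normalized to unit area, implemented as
a discrete sum over 1-bp length bins: fragment lengths are integers, so
unit-area normalization is exactly sum-to-one and a class "area under the
curve" is the summed density over an inclusive length range. The default
classes are nucleosomal (141-250 bp) and supernucleosomal (251-428 bp),
both configurable. The headline statistic is the ratio-of-ratios: the IP
sample's supernucleosomal/nucleosomal AUC ratio divided by the input's,
which isolates IP-specific enrichment of long protections from overall
digestion differences. Group comparisons of per-sample ratios use a
two-sided Welch (unequal-variance) t-test; the test is stated prominently
because published ratio comparisons of this kind often omit which test was
used. Groups are supplied by the caller, since pooling choices (samples
per factor, per digestion time) are study-specific.

# V-plots

A V-plot bins (signed midpoint distance from an anchor, fragment length)
pairs on a 2-D grid. The default grid is x in [-1000, +1000] bp at 5-bp
bins (401 bins) by 400 consecutive 1-bp length bins starting at 25 bp --
160,400 bins in total, with percent normalization defined as
`100 * count / contributing fragments` so the matrix totals 100. The
length window 25-424 bp is an inference from the bin total and the
smallest recoverable fragment of the library protocol this grid emulates;
anyone comparing pixel-level output to published figures should check the
y-window first, and both axes are fully configurable.

X bins are centered on multiples of the bin width: a distance d maps to
bin `k = round(d / x_bin)` with exact ties rounded away from zero. A
left-edge `floor()` rule was considered and rejected because it is not
mirror-symmetric about x = 0 -- reflecting every anchor to the opposite
strand would not exactly mirror the matrix, which we treat as a hard
invariant (and test). With centered bins and integer midpoints the mirror
identity is exact. Fragments near two anchors contribute to both
(pair-wise counting), and distances exactly at the window edge are
included.

# Signal profiling

Coverage tracks count, at every base, the fragments whose interval
contains it; the genome-wide total therefore equals the summed fragment
lengths, which is asserted as a conservation test. The log2(IP/input)
track first scales both coverage tracks to a common effective depth (their
mean total) -- the minimal interpretation of "input-normalized" -- then
computes `log2((ip + c) / (input + c))` with pseudocount `c = 0.5`
post-scaling counts by default. Bases with zero raw coverage in both
samples are masked and excluded from every downstream average. We compute
per-base log ratios and then average across anchors; the alternative
(ratio of averaged coverages) weights high-coverage anchors more and is
not what we do.

Aggregate profiles average the track over anchors at each offset of a
+/- 1 kb window (the default gene window), excluding masked and
out-of-bounds bases from numerator and denominator alike. Quintile
profiles rank anchors by their mean window signal; group sizes differ by
at most one, remainders go to the top groups, and ties break by anchor id,
making the output fully deterministic. Heatmaps order rows by a named
per-gene metric, descending, ties again by id. Low-resolution metrics
(e.g. nucleosome turnover measured on arrays) are compared through
`windowed_track()`, non-overlapping 40-bp block means by default, with
all-masked windows staying masked.

The NDR diagnostic regresses the maximum log-ratio inside each
nucleosome-depleted region on NDR width (ordinary least squares,
R-squared reported). A large R-squared would indicate that apparent
binding merely tracks the amount of exposed DNA; the simulator's designed
null is a per-gene enrichment drawn independently of NDR width, for which
the fitted R-squared is expected near zero. One subtlety the test suite
encodes: a naive "random signal everywhere" null is *not* independent --
the maximum over a wider interval of i.i.d. values is stochastically
larger, which alone produces R-squared around 0.05-0.08. Designed
independence requires one signal peak per NDR.

# Sequence composition and bendability

Position frequency matrices count A/C/G/T per position of strand-oriented
anchor windows (minus-strand anchors contribute reverse-complemented
sequence); ambiguous bases are excluded from the four base rows and
tallied separately so that column sums always conserve the sequence
count. The per-position A+T fraction is the logo-style summary used for
centromere composition.

Bendability scoring assigns each trinucleotide's scale value to its
central base and smooths with a 39-bp sliding window mean; positions whose
window does not fit in the sequence are undefined, and trinucleotides
containing ambiguous bases are dropped from the window mean rather than
poisoning it. The packaged scale is the DNase I-derived consensus
trinucleotide bendability table (strand-symmetric, 64 entries); the scale
is a pluggable TSV because different servers and papers use different
tables, and only the bendability mode is implemented (curvature propensity
is a different model and out of scope). Class comparisons summarize each
region by its mean defined profile value and apply a two-sided Welch
t-test; the packaged synthetic analogue mirrors the 29-regions-per-class,
100-bp-region design of the site-class comparisons this analysis is
typically used for.

# The synthetic chromatin simulator

The simulator is first-class, tested code; its defaults define the study
conditions the test-suite recovery checks assume.

**Genome.** Background sequence is i.i.d. at G+C 0.38 (the budding-yeast
average). The demonstration layout places gene cassettes -- a promoter NDR
with a TFBS centered inside, then a 1.2-kb ORF, strands alternating -- plus
a tail of 200-bp point centromeres (CDEI 8 bp / CDEII 160 bp / CDEIII
32 bp element fills averaging ~0.90 A+T over the body, emulating the
extreme A+T-richness of yeast point centromeres) and two classes of 29
100-bp "remodeling site" regions at 0.85 and 0.50 A+T for the bendability
contrast. Same-class features may never overlap; violations are rejected
with coordinates.

**Chromatin.** Dyads tile inter-NDR spans at the nucleosomal repeat
(default 165 bp against a 147-bp core, hence 18-bp linkers; 154 bp gives
the 7-bp-linker regime). Arrays are phased off NDR boundaries -- the
flanking core edge abuts the boundary -- and a span between two NDRs is
phased from both ends, meeting near its middle with at least one core
length of separation; an NDR-free chromosome is tiled uniformly from its
start. Each TFBS yields a TF footprint (site plus 5 bp padding) and two
candidate one-sided remodeler-spanning protections running from a flanking
nucleosome core, across the intervening linker, to the far edge of the
TFBS: protection of linker DNA on one *or* the other side of the factor,
chosen per emitted fragment.

**Digestion.** MNase is modelled as per-end exponential nibbling: each end
of the maximal protected span (unit plus its linker/padding overhang) is
trimmed inward by an independent `Exp(scale)` draw, floored to whole
base pairs. One parameter reproduces the digestion-extent phenomenology:
the modal emitted length of a unit of maximal span L is approximately
`L - scale`, so a 147-bp core with 18-bp overhangs (span 183) peaks near
170 bp at `extent = 13` and near 160 bp at `extent = 23`, and mean length
decreases strictly with extent. Fragments below the 25-bp minimum (or
above the configured maximum) have their trims redrawn.

**Enrichment.** Units are sampled with replacement by class weight. In IP
samples the remodeler-spanning class is multiplied by `supernuc_boost`
(default 2.5), which is therefore the designed supernucleosomal AUC
ratio-of-ratios up to class-leakage at the 250/251-bp boundary (measured
recovery at 200,000 fragments is ~2.4). The input chromatin's
supernucleosomal baseline is not dictated by the phenomenology the
simulator emulates, so it is an explicit parameter
(`input_span_weight`, default 1 per unit) rather than a constant.
Optional per-gene enrichment scores modulate IP weights of all units
within +/- 1 kb of a gene 5' end by `2^score`; this modulation is
renormalized within each unit class so the class mix -- and hence the
designed boost -- is unchanged. Gene metrics (expression, turnover,
transcription rate) are linear transforms of
`coupling * score + sqrt(1 - coupling^2) * noise` on a latent Gaussian
scale, so the realized Pearson correlation with the designed enrichment
equals the coupling target up to sampling error; a nonlinear
(e.g. lognormal) transform would attenuate the correlation and was
avoided deliberately.

All randomness flows from one integer seed through fixed per-operation
streams; identical seeds give byte-identical outputs, and every emitted
fragment carries a provenance record (source unit, class, extended source
interval) in a sidecar table so that ground-truth containment is testable
without polluting the BED output.

**What the simulator does not emulate.** Sequencing errors and base
qualities, mappability, GC amplification bias, chromatin heterogeneity
between cells, rotational nucleosome positioning, and inter-nucleosome
spacing variability (arrays are perfectly phased). Passing recovery tests
therefore demonstrates correctness of the analysis arithmetic under the
stated generative model, not robustness to every artifact of real
libraries.

# Pipeline and reproducibility

`run_pipeline()` drives everything from one YAML config (template in
`inst/extdata/demo_config.yaml`) with exactly one data source: the
simulator section or user-supplied files. Unknown keys are rejected by
name; defaults are materialized so a validated config re-validates to
itself. Every output file records the config MD5 hash and seed in a
header comment, and all outputs are byte-identical across runs of the
same config and seed (the run log carries wall-clock timings and is the
documented exception). The full demonstration run -- ~1 Mb genome, 500
gene cassettes, 200,000 fragments per sample, all stages -- completes in
well under a minute on one CPU; the test suite runs the same
configuration and asserts completion within its time budget.

Problem sizes used by the test suite were chosen to keep each recovery
check statistically decisive at a fixed seed: 200,000 fragments for AUC
ratio recovery (sampling error ~0.01 on the ratio-of-ratios), 500 NDRs
for the independence regression, 1,000 genes for coupling recovery, and
brute-force oracle comparisons at up to 10^4 elements.

# Known limitations

* BEDPE parsing collapses mate pairs to the spanning interval and skips
  (with a count) pairs on different chromosomes; no other filtering is
  applied, and upstream MAPQ/duplicate handling is accepted as-is.
* Chromosome name matching is exact; no alias table.
* The AUC ratio-of-ratios recovery is biased slightly below the designed
  boost by trimming leakage across the fixed 250/251-bp class boundary;
  the bias shrinks as protections sit deeper inside the supernucleosomal
  window.
* `ndr_correlation()` reports plain OLS R-squared; it is a diagnostic,
  not a calibrated hypothesis test.
* Percent V-plot export uses fixed 6-decimal formatting; counts export is
  exact.
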