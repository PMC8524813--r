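---
title: "Quantifying broad histone-mark enrichment at satellite DNA repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying broad histone-mark enrichment at satellite DNA repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satrep)
```

## The problem

H3K9me3 is the canonical repressive histone mark of constitutive
heterochromatin. Unlike transcription-factor ChIP-seq, its signal forms
broad, flat domains without sharp summits, so peak-centric workflows
describe it poorly. satrep quantifies this mark (or any broad mark) at
*individual annotated satellite DNA instances* — RepeatMasker-annotated
copies in the assembled genome, including elements far from
(peri)centromeres — and asks where the mark differs between biological
states: normal versus cancer cell lines, or successive fetal developmental
stages across tissues.

Satellite arrays are also the classic source of ChIP-seq artifacts: they
dominate blocklists of anomalous-signal regions, and reads from them often
map to many genomic positions (MAPQ = 0). The pipeline therefore treats
instance selection, ambiguous-read diagnostics, and a consensus-based
re-analysis of the unmappable fraction as first-class stages rather than
afterthoughts.

## Enrichment model

For element $e$ and a paired ChIP/input sample, with $\bar s_{chip}(e)$ the
length-weighted mean track signal over the element and $m_{chip}$ the
genome-wide per-base median of the ChIP track (likewise for input):

$$
\mathrm{FC}(e) \;=\;
\frac{\bar s_{chip}(e)/m_{chip} + 1}{\bar s_{input}(e)/m_{input} + 1},
\qquad
\mathrm{enrichment}(e) \;=\; \max\{0,\ \log_2 \mathrm{FC}(e)\}.
$$

The median normalization absorbs sequencing-depth differences between
samples (the whole statistic is invariant under independent positive
rescaling of either track — a property the test suite asserts to 1e-9).
The +1 pseudocount keeps the ratio defined on sparse tracks, and the clamp
at zero encodes the judgement that loci where input exceeds ChIP carry no
true signal. Values are stored in an elements × samples matrix alongside
sample metadata. For datasets distributed as precomputed fold-change tracks
(merged-replicate ChIP/input ratios), the per-element value is instead the
length-weighted mean linear FC; both the linear value (for stage-level
summaries) and its clamped log2 (for the matrix) are retained.

**Numerical conventions.** All coordinates are 0-based half-open
throughout; touching intervals do not overlap, and "any overlap" with the
blocklist means at least one shared base. The genome median is computed
from run lengths without base expansion, counting uncovered bases as zero
(`include_zeros = TRUE` by default — density tracks leave gaps, and a
defined convention is required; the flag exists because the alternative,
covered-bases-only, is defensible for pileup-style tracks). The even-count
median is the mean of the two central order statistics. A zero median is a
hard error rather than a silent division by zero. Negative run values,
which some track dialects emit, are floored at zero on read with a warning.

## Instance selection

`read_rmsk()` consumes UCSC-style RepeatMasker tables (bin column
auto-detected), keeps the configured repeat class (default `Satellite`),
and assigns deterministic ids `chrom:start-end:name`. `filter_blocklist()`
removes every instance sharing at least one base with a blocklist interval;
`filter_chromosomes()` drops sex chromosomes (so male- and female-derived
samples are comparable) or restricts to a custom set. Subfamily names are
kept verbatim as annotated — no normalization of naming variants is
attempted.

## Differential enrichment

*Two groups* (e.g. normal vs cancer): a per-element Welch unequal-variance
t-test on the clamped log2 FC values. The headline set uses unadjusted
p < 0.05: with a broad mark, thousands of weakly dependent elements and
modest sample counts, Bonferroni across elements is extremely conservative,
so the adjusted flags are reported alongside rather than substituted. The
per-element group means, their +1-transformed ratio and a relevance flag
are emitted too, so a stricter intersection ("significant and relevant")
costs one filter expression downstream.

*Stages* (e.g. developmental time course, tissues as replicates): per
element, one-way ANOVA across stages, Bonferroni correction across
elements, Tukey HSD (Tukey–Kramer for unequal group sizes) on elements with
adjusted p < 0.01, and a relevance screen. The screen exists because an
element whose log2 FC is, say, 0.10 in one stage and 0.01 in another can be
extremely significant yet biologically meaningless (both values mean
"FC ≈ 1"). Per-stage means are therefore +1-transformed and the pairwise
ratio (larger direction, inclusive) must reach 1.5. An element is reported
iff at least one stage pair is both Tukey-significant and relevant — a
monotone chain ANOVA → post hoc → relevance that the suite asserts as an
invariant.

Degenerate inputs follow stated conventions rather than NaN propagation:
identical groups give p = 1; zero within-variance with distinct means gives
p = 0 with a `degenerate` flag; all-zero rows are tested and flagged.

Family over-representation among the differential set uses the upper-tail
hypergeometric test with fold = (k/n)/(K/N).

The row-wise Welch and ANOVA statistics are computed from closed-form
sums of squares, vectorised over elements (needed to run 10,000-replicate
null calibrations in seconds); `stats::t.test`, `stats::aov` and a direct
studentized-range computation serve as independent oracles in the tests,
which also verify type-I calibration within the 99% binomial interval and
KS-uniformity of null p-values.

## Sample-level structure

PCA is run on samples (elements as variables, autosome-only, row-scaled
with zero-variance rows removed; component signs fixed so the
largest-magnitude loading is positive, for reproducible score tables).
Group separation is tested by PERMANOVA on a binomial dissimilarity
between samples,

$$ d(x,y) = \sum_i \big[ x_i \log(x_i/n_i) + y_i \log(y_i/n_i) + n_i \log 2 \big],
\quad n_i = x_i + y_i, $$

with $0\log 0 := 0$ and all-zero elements contributing nothing; the
clamped log2 FC matrix is non-negative as this index expects. (The common
ecological implementation divides each term by $n_i$; the definition above
is the unscaled form and is fixed here explicitly since named
implementations differ.) The PERMANOVA pseudo-F uses the standard
among/within partition of squared dissimilarities; p is
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ with free label
permutation (no strata), and an explicit permutation matrix can be supplied
— the tests exploit this to match an exhaustive 6-sample enumeration
exactly and to cross-check the pseudo-F against `vegan::adonis2`. By
default the dissimilarity is computed on the raw (unscaled) non-negative
matrix; a scaled variant can be produced by composing with `scale_rows()`.

## Ambiguous reads and consensus re-mapping

`mapq0_fraction()` reports, per element, the fraction of overlapping reads
with MAPQ = 0 together with the supporting read count, so low-support
elements (e.g. fewer than 6 reads) can be flagged. For satellites too
repetitive to analyze positionally, the re-mapping stage: removes duplicate
and unmapped reads, merges replicates, downsamples ChIP and input to the
same read count (exact, uniform, seeded), extracts MAPQ-0 reads and aligns
them end-to-end to *consensus dimers* — each family's monomer concatenated
to itself so reads spanning the monomer junction can align. Per-family
enrichment is the ratio of aligned-read counts, defined only at equal
totals (unequal totals are an error because they defeat the
normalization).

The built-in matcher is deliberately simple and fully specified: a read
aligns if some ungapped end-to-end placement on the dimer (either strand)
has a mismatch rate ≤ 0.1; N counts as a mismatch; the best family wins
and cross-family ties are discarded as unassignable. It is implemented as
a one-hot-encoding matrix product over all placements (fast and exact) and
is verified against a brute-force all-placements oracle. Users with a real
aligner can ingest its SAM via `read_alignments()` +
`count_sam_by_reference()` instead. Per-position dimer coverage is
accumulated and a max/mean uniformity statistic (> 10 flags) marks
families whose "alignments" pile onto a short low-complexity segment
rather than covering the repeat — such apparent enrichment should not be
trusted.

## Secondary overlap analyses

Called-peak concordance uses 50% reciprocal overlap, optionally restricted
to elements with linear FC ≥ 2 (clamped log2 FC ≥ 1). RNA contig levels
(BPKM/RPKM) are averaged per element, unweighted by default
(`overlap_bp` weighting available); any overlapping contig counts as
transcription evidence, and contigs fully contained in an element are
book-kept separately. Chromatin-state composition tallies overlap bases
per state, with an explicit `unsegmented` bucket and genome-wide state
totals for relative representation. Nucleosome occupancy compares observed
per-element mean MNase signal against a null of uniformly re-placed
coordinates (`shuffle_intervals()`, rejection sampling that is exactly
uniform over allowed positions) and reports both Pearson and Spearman
correlation with enrichment, since "no correlation" should not hinge on
linearity. Gene overlap is ≥ 1 bp.

## The synthetic dataset generator

`simulate_satellite_dataset()` emits a complete miniature dataset — rmsk
table, blocklist, per-sample tracks, SAM read sets, consensus FASTA, RNA
contigs, segmentation, peaks, genes, metadata — plus a ground-truth table,
byte-identical under a fixed seed. It exists so that every stage of the
pipeline, including file parsing, runs and is validated at desk scale
without any external downloads.

What it emulates: element-level enrichment with group- or stage-dependent
planted effects; a tight pericentromere-like cluster of one family
(partially blocklisted at its core) next to dispersed singles; background
coverage as a smoothed gamma-tile field (realistic piecewise-constant
bedGraph runs, per-sample depth factors); signal spreading into cluster
flanks; elevated multimapper fractions at the cluster; tandem-repeat reads
drawn from consensus dimers with 2% per-base mutation, plus a
low-complexity family whose reads pile onto a short segment; RNA contigs
that always extend past element boundaries; genes, peaks and a chromatin
segmentation with known per-element truth.

The element-level signal model draws the target clamped log2 FC per
element and sample first — $v_{es} = \max(0,\ \mu_{es} + \varepsilon)$,
$\varepsilon \sim N(0, \sigma_w)$ — and then constructs the ChIP run over
the element so the measured enrichment reproduces the draw (exactly in
fold-change-track mode; in paired mode up to the small genome-median shift
the element runs themselves induce, < 0.01 log2 units at the default
geometry). Randomness therefore lives in the planted draws, which keeps
power calculations for the recovery tests exact, while the background
field still exercises the run-length code paths. This is also the model's
main idealisation: real tracks add within-element measurement noise,
sample-level covariance and copy-number structure that the generator does
not emulate, so passing recovery tests demonstrates correctness of the
pipeline's computations, not performance on real data.

Scenario defaults are the study conditions and are not tuning knobs:

* `cancer_hypomethylation` — 13 normal vs 8 cancer paired-track samples;
  200 analyzed autosomal elements (170 dispersed + 30 in a GSATII-like
  cluster), 20 true positives (12 in the cluster) with
  $\Delta \log_2 FC = 1.0$, within-group sd 0.3; element baselines
  $\max(0.05, N(0.6, 0.25))$, matching the overall enrichment level
  reported for such panels; additional blocklisted (cluster core plus
  dispersed), sex-chromosome and non-satellite rows exercise the filters.
* `fetal_wave` — 8 stages × 9 tissues = 72 fold-change-track samples;
  20 true positives following a wave trajectory (highest at the earliest
  stage, sharp drop, partial mid-gestation recovery, low again before and
  at birth) with transformed stage-mean ratio
  $(m_{hi}+1)/(m_{lo}+1) = 2.0$; 14 of the 20 belong to one
  MMSAT4-like family of 24 annotated instances, so full recovery implies
  a ~5.8-fold family over-representation; consensus read sets carry 3×
  (major satellite) and 2× (minor satellite) planted ChIP/input
  enrichment at equal downsampled totals, five further families receive
  no reads.

Problem sizes (a few-Mb toy genome, hundreds of elements, thousands of
reads) were chosen so a full two-scenario analysis completes in well under
a minute while every statistical property of interest — calibration,
power at the planted effect sizes, binomial sampling error of count
ratios — is still measurable.

## Known limitations and open choices

* The test scale for differential analysis is the clamped log2 FC matrix;
  testing on linear FC is a documented alternative (`test_scale` thinking),
  but clamped log2 is what the enrichment heatmaps and density summaries
  use, so it is the default and only implemented scale.
* Tissues within a stage are treated as independent replicates; no nesting
  or mixed-model structure is modelled.
* Whether PERMANOVA should see raw or row-scaled values is genuinely open;
  raw is the default because the binomial index requires non-negative
  input.
* The clamp at zero makes low-baseline null distributions semi-discrete;
  the Welch test remains calibrated in simulation, but exact small-sample
  behaviour on heavily clamped rows is approximate.
* The built-in consensus matcher is ungapped; reads with indels relative
  to the consensus under-align. The external-SAM path exists for exactly
  that case.
* Per-sample alignment-rate statistics of real libraries depend on the
  actual read composition and are not reproduced by the generator's
  simplified read mix.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config("cancer_hypomethylation", seed = 1)
bundle <- simulate_satellite_dataset(cfg)
write_dataset(bundle, "dataset")
res <- run_pipeline("dataset", "results", seed = 1)
res$report
```

The same two commands are available from a shell via the thin wrapper in
`inst/scripts/satrep` (`satrep simulate ...`, `satrep run ...`), and
`scripts/acceptance.R` recomputes the headline quantities of both
scenarios from scratch into a JSON file.
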