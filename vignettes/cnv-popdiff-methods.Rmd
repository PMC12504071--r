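---
title: "Methods: read-depth CNVR discovery and copy-number population differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNVR discovery and copy-number population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cnvpopdiff` builds a copy-number-variation-region (CNVR) map from
windowed short-read depth and contrasts two populations with the Vst
statistic. This vignette explains the model behind each stage, the
parameters that matter, what the bundled simulator does and does not
emulate, and the design decisions taken where several reasonable
choices existed.

## The read-depth model

Whole-genome resequencing depth is, to first order, proportional to the
underlying copy number: a diploid region sequenced at depth $d$ yields
on average $d \cdot \mathrm{CN}/2$ of its expected read count. The
package therefore tiles autosomes into fixed windows (default 800 bp,
advanced by 400 bp so consecutive windows half-overlap), counts each
aligned read into every window containing its alignment midpoint, and
converts normalized counts to copy numbers by scaling each sample so
its median window sits at CN = 2. Only autosomes are tiled by default:
the diploid-background assumption does not hold for sex chromosomes,
which sit behind the `include_sex` flag.

The midpoint rule gives each read a single well-defined location, so a
read contributes to at most two of the half-overlapping windows and
long reads are not over-counted at window edges. Coordinates are
0-based half-open everywhere internally and in all BED output.

Two systematic effects are handled before the copy-number conversion:

* **Read quality.** `qc_filter()` drops reads with at least 10%
  undetermined bases, reads in which more than half the bases have
  Phred quality at or below 20, and reads containing a configured
  adapter verbatim; mates are dropped as pairs. The N-fraction rule is
  inclusive (exactly 10% fails) and the low-quality rule is strict
  (exactly 50% passes); the filter is idempotent.
* **GC bias.** Depth depends on window GC content through library
  preparation and sequencing chemistry. `gc_normalize()` bins windows
  by GC fraction (bins of 0.01) and rescales each sample's counts so
  every bin's median matches the sample's global median. Bins with
  fewer than 20 windows, and bins whose per-sample median is zero, are
  masked (`NA`) rather than rescaled by an unstable factor; masked
  windows are excluded from every downstream step. Median-ratio
  scaling is used instead of a fitted curve because it is
  distribution-free and exact at the statistic the caller uses (the
  median).

## CNVR calling

A window is a **candidate** when the fraction of samples with copy
number at or above `gain_cn` (2.5) or at or below `loss_cn` (1.5)
reaches `min_carrier_frac` (0.1, inclusive; missing samples leave both
numerator and denominator), *and* its copy numbers correlate across
samples (Pearson r at least 0.5) with at least one of its nearest
non-overlapping neighbor windows. The correlation test exists because
a real copy-number change spans several windows and imprints the same
sample ranking on all of them, while counting noise does not. At a
typical 10x depth (roughly 50 reads per 800 bp window) the per-window
copy-number noise is large enough that the carrier-fraction rule alone
flags a substantial share of diploid windows; requiring the
multi-window signature removes almost all of them while leaving real
loci intact. The neighbor is the nearest *non-overlapping* window
because half-overlapping neighbors share reads in real alignments,
which would correlate their noise and defeat the test. The test can be
disabled (`neighbor_cor = NULL`).

Candidates are merged into regions: maximal runs of flagged windows on
one chromosome, tolerating one unflagged window inside a run
(`max_gap_windows = 1`, a conservative smoothing of isolated dropouts),
with at least two flagged windows per region — consistent with the
smallest CNVR observable at this window geometry (about 1.6 kb).

Each region is then genotyped: per sample, the mean copy number over
the region's unmasked windows, rounded **half-up** to an integer
(2.5 becomes 3; deterministic across platforms, unlike banker's
rounding). Carriers are samples whose integer copy number differs
from 2. Classification is exhaustive and exclusive: `duplication` when
all carriers are above 2, `deletion` when all are below, `both`
otherwise. A region must retain the same carrier fraction at genotype
level that its candidate windows were required to show
(`min_carrier_frac`, degenerating to "at least one carrier" when set
to 0); without this, rare chance pairs of correlated noise windows
survive as single-carrier regions. Finally, class-specific length
limits are applied: deletion and mixed regions up to 50 kb
(inclusive), duplications below 500 kb (exclusive) — the limits
conventionally used with this windowed calling approach.

CNVRs are called jointly on all samples in a single matrix rather than
per population and then united; joint calling gives every sample a
genotype at every region, which the differentiation statistic needs.

## Vst

For per-sample copy numbers split into populations of sizes $N_1$ and
$N_2$:

$$
V_{ST} \;=\; \frac{V_{total} - \big(V_{pop1} N_1 + V_{pop2} N_2\big)/N_{total}}{V_{total}}
$$

All variances are *population* variances (divide by $N$, not $N-1$).
With that convention the size-weighted within-population variance is
exactly the within-group term of the law of total variance, so
$V_{ST}$ equals the between-group variance fraction and always lies in
$[0,1]$: 0 for identical copy-number distributions, 1 for a fixed
difference. Sample variances ($N-1$) would break this identity and
allow values outside the unit interval, which is why population
variances are the default (the choice is exposed for sensitivity
analysis). When $V_{total} = 0$, $V_{ST} = 0$ by convention. Missing
genotypes are dropped per region and the $N$s recomputed from the
non-missing samples; a region with fewer than two informative samples
in either population gets `NA` rather than a misleading value.

Vst is computed on the real-valued per-sample mean copy numbers by
default — rounding to integers discards information — with an
`integer_cn` switch for the rounded alternative.

**Top-fraction selection.** The `ceiling(fraction * M)` records with
the largest Vst are flagged, where `M` counts non-missing records and
`fraction` defaults to 0.01. `ceiling` reproduces the conventional
"top 1%" counting (5,599 regions yield 56 selected). Ties at the
threshold break by chromosome order then start position, so the
selection is deterministic and exactly `k` records are flagged.

## Structure summaries

The per-CNVR copy-number matrix doubles as a genotype matrix for
structure summaries, which keeps the pipeline self-contained (no
external genotype calls are needed):

* **GRM**: columns centered by their means (missing entries
  mean-imputed first), $K = WW^\top/m$ — symmetric and positive
  semidefinite by construction.
* **PCA**: eigen-decomposition of the centered sample covariance;
  variance explained is each eigenvalue as a percentage of the trace.
* **Tree**: neighbor joining on the mean absolute copy-number
  difference over shared non-missing CNVRs. The Manhattan-type
  distance is robust to a single region with a large copy-number
  excursion, which would dominate a squared distance. Both the
  distance and the method are standard, so the implementation
  delegates to `ape`.

## Annotation and enrichment

Selected regions are intersected with gene models (BED or GFF3,
converted to 0-based half-open on load); a gene is reported when the
half-open intervals share at least one base, strand ignored, and genes
are deduplicated across regions before counting. Gene-body overlap
only is used, with a configurable flank defaulting to 0 bp.

Term enrichment is a one-sided hypergeometric test per term
($P(X \ge k)$ with background $N$, term size $K$, study size $n$,
overlap $k$) with Benjamini–Hochberg adjustment across terms and
significance at adjusted $p < 0.05$. Annotation is a user-supplied
offline table (`gene_id`, `term_id`, `term_name`), so results are
reproducible without live database access; the background defaults to
every gene in the table and can be overridden.

## The simulator

`simulate_depths()` generates the data the test-suite validates the
pipeline against: two populations (defaults 13 and 15 samples), window
counts drawn from a negative binomial whose expectation is
`mean_depth * (CN/2) * g(GC)`, and planted CNV loci with
population-differentiated copy-number frequencies.

Default conditions, chosen once to model a realistic two-breed
resequencing design:

* `mean_depth = 53` reads per window — 10x coverage of 150 bp reads
  counted by midpoint in 800 bp windows ($10 \times 800 / 150$).
* `dispersion = 250` (negative-binomial size) — about 20% extra
  variance over Poisson at this depth, a typical residual after GC
  correction; `Inf` gives pure Poisson.
* GC per window from Beta(14, 18) (mean 0.44), and a hump-shaped
  quadratic bias $g$ with coefficients $(-0.3, 6, -6.6)$, normalized
  to mean 1 over windows. This injects the bias the normalization
  stage must remove.
* 30 loci on a 2 x 5 Mb genome, lengths log-uniform on 1.6–282 kb,
  with deletion and mixed loci capped at 50 kb to match the
  class-specific length rules; at least 4 kb apart so calls cannot
  bridge adjacent loci.
* Per locus, one population carries the alternative copy number at
  frequency uniform on 0.5–0.95 and the other at 0–0.3, giving a
  spread of true Vst values with every locus segregating. Integer
  copy numbers are drawn i.i.d. from these per-population tables —
  Vst operates on copy numbers directly, so no allele-level
  Hardy–Weinberg structure is imposed.

Windows fully inside a locus carry the sample's locus copy number;
partially overlapping windows stay diploid. A single seed governs all
draws, with per-sample sub-streams derived deterministically from it,
so runs are byte-identical and adding samples does not perturb
existing ones. The truth channel (BED loci, integer copy-number
matrix, true Vst computed from an inline variance decomposition kept
independent of `vst()`) makes every downstream stage testable.

What the simulator deliberately does **not** model: read-level errors,
mappability and duplicated-window structure, fractional copy numbers
at locus boundaries, linkage between loci, and sex chromosomes. Counts
are drawn independently per window, whereas real half-overlapping
windows share reads and correlate their noise. Passing tests therefore
show that the statistical machinery recovers planted signal under the
stated depth model — not that the caller is robust to alignment
artifacts of real genomes, where the optional exclusion-mask input and
the duplicated-window handling of purpose-built callers matter. The
ambiguous merged-segment preprocessing used by some callers is
likewise replaced by an optional user-supplied exclusion mask rather
than guessed.

## Numerical choices and degenerate inputs

* Round-half-up for integer genotypes; no randomized tie-breaking
  anywhere.
* Vst is clamped to $[0,1]$ against floating-point drift; the
  decomposition identity itself holds to machine precision.
* All-zero samples fail GC normalization loudly; zero-median samples
  fail copy-number conversion; all-missing windows are unflagged; a
  constant copy-number matrix yields a zero GRM with a warning.
* Chromosomes shorter than one window tile to zero windows; a
  trailing partial window is omitted rather than truncated.
* The correlation test needs at least three shared samples per window
  pair; windows without an eligible neighbor fail the test rather
  than passing silently.

## Problem sizes in the test-suite

The validation suite runs the full pipeline on a 2 x 5 Mb genome with
28 samples (about 25,000 windows), where recovery of the 30 planted
loci, Vst accuracy against truth, bias removal, and the
population-structure summaries are checked end to end; unit tests use
toy grids of a handful of windows with hand-computed expectations.
These sizes were chosen so the whole suite exercises every stage at
study-like depth while remaining quick to run.

## Limitations

Breakpoints are window-quantized (multiples of the step size), so
region boundaries are coarse. The caller genotypes by rounding mean
copy number, which is adequate for well-separated integer states but
not a likelihood model for mosaic or multi-allelic loci. Vst carries
no significance machinery — the top-fraction rule is a ranking, not a
test — and enrichment inherits whatever bias the user's annotation
table has. Real-data artifacts (mappability, reference errors,
paralog collapse) must be handled upstream via the window exclusion
mask.
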