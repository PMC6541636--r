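---
title: "Methods: two-condition peak redistribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition peak redistribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakshift)
```

peakshift compares the genomic distribution of a chromatin mark — the
motivating case is the histone variant H2A.Z in control versus mutant
peripheral nerve — between two conditions, starting from per-condition peak
calls, replicate coverage and per-region counts. This vignette documents the
statistical procedure, the tunable parameters, the synthetic data the test
suite runs on, and the numerical and design decisions a maintainer should
know about.

## Coordinate and data model

All interval tables are tibbles with `chrom`, `start`, `end` in 0-based
half-open coordinates, the convention of BED and bedGraph. GTF/GFF3 input
(1-based, inclusive) is converted on read. The TSS of a plus-strand
transcript is the interval start; of a minus-strand transcript, `end - 1`.
Coverage tracks are sparse step functions (intervals with a value; gaps are
zero) with chromosome sizes attached, and per-region counts live in a small
`count_matrix` object carrying condition labels and library sizes.

## Peak partition

A peak is *shared* when it overlaps a peak of the other condition by at
least `min_overlap` bp (default 1 bp — the most permissive reading, since
peak callers rarely agree on exact boundaries). Shared peaks are matched
one-to-one by greedy mutual maximal overlap: all overlapping candidate pairs
are ranked by overlap (largest first), ties broken by the distance between
summits (midpoints when the caller reported none), then by leftmost
coordinates, and each peak joins at most one pair. The greedy order makes
every accepted pair the best remaining match for both members, and the
deterministic tie-breaks make the partition reproducible and independent of
input order. Peaks that overlap something but lose every pairing fall to the
condition-specific sets rather than forming chains; this keeps the
width/height comparison of shared pairs well defined. One-to-one pairing was
a genuinely open choice — interval-join tools used for this kind of analysis
do not define a pairing — and is the package's own convention.

## Signal summaries and 1× normalization

Replicate coverage is scaled so mean coverage over the effective genome is
exactly 1 (`normalize_to_1x()`): output = input × (effective genome size /
total mass). The effective genome size is an explicit argument, not
inferred, so results are deterministic across input subsets. Normalization
is idempotent and linear; the unit tests check genome mean 1 within 1e-9 and
idempotence within 1e-12.

Peak *height* is the across-replicate mean of a per-replicate summary of
normalized coverage over the peak. The default summary is the mean (robust
to single-base spikes and directly interpretable on the 1× scale); the
maximum is available via `height_stat = "max"`. Heights are computed per
condition from that condition's replicates, i.e. on replicate-averaged
signal — whether shape criteria should instead be met in every single
replicate is an open question in this kind of analysis; the averaged form is
the package's choice and is stated here rather than hidden.

TSS matrices bin ±2.5 kb windows (default) into 50 bp bins — standard
metaprofile resolution, configurable — with minus-strand rows reversed so
upstream is always left, zero-padding and a flag for windows clipped at
chromosome ends, and row ordering by total signal for the
strongest-at-top heatmap convention.

## Shape classification of shared peaks

With thresholds `width_delta_bp = 1500` and `height_fold_delta = 1`, a
shared pair is *broader* when the mutant peak is ≥1.5 kb wider, *higher*
when the mutant/control height ratio is ≥ 2, and *narrower*/*lower*
symmetrically (ratio ≤ 0.5, ≥1.5 kb narrower). A pair is `broader_higher`
when it meets broader or higher and neither opposite criterion;
`narrower_lower` symmetrically; everything else — including pairs with
conflicting width and height evidence — is `unchanged`.

Two readings of "1-fold higher" exist: a 100 % increase (ratio ≥ 2) or any
increase (ratio ≥ 1). The package defaults to the doubling reading, which we
consider the plausible one, and exposes `height_fold_delta` so the other is
one argument away. Conflicts map to `unchanged` because the criteria define
no priority between width and height; inventing one would silently bias the
class balance. Degenerate heights are handled explicitly: zero control with
positive mutant height gives an infinite ratio (higher, with a warning);
both zero gives ratio 1.

Classification is antisymmetric by construction: swapping the condition
roles swaps `broader_higher` and `narrower_lower` and fixes `unchanged`
(property-tested).

## Differential occupancy

Rather than a negative-binomial GLM, differential occupancy uses a
transparent permutation test that is assumption-light at quadruplicate
scale: per region, counts become `y = log2(CPM + 0.5)` (CPM = count /
library size × 10⁶; the 0.5 pseudo-count is a standard continuity
correction), the statistic is the difference of condition means of `y`
(which is also the reported log2 fold change, so the sign of the call and
the fold change can never disagree), and the two-sided p-value comes from
the exact permutation distribution over all condition-label reassignments —
70 arrangements for 4 vs 4 — or from 10⁴ seeded Monte-Carlo permutations
when enumeration would exceed 10⁴ arrangements. BH adjustment runs across
all tested regions; calls threshold the unadjusted p at α = 0.05 by
default, with `call_on = "adjusted"` available, and the adjusted p is always
reported.

**Calibration ceiling.** An exact two-sided permutation p at 4 vs 4 can
never be smaller than 2/70 ≈ 0.0286 (the observed labelling and its mirror
always count), so the achievable test size at α = 0.05 is at most 2/70;
count ties push it lower. Empirically the type-I error on a Poisson null at
2000 regions sits near 0.02–0.03 — the test is conservative, which is the
price of exactness at small replicate numbers, not a defect. Any check
expecting the nominal 0.05 to be attained within a narrow band will
therefore read low; the acceptance suite reports this number as measured.

## Gene annotation and integration

The genome-wide promoter list is one ±1.5 kb window per distinct TSS,
clipped at chromosome bounds, with overlapping windows of the same gene
merged (windows of different genes are kept separate). Because multi-TSS
handling is ambiguous in this kind of pipeline, both "all TSSs" (default,
a conservative superset) and "first TSS only" modes exist. Regions are
labelled promoter when their distance to the nearest TSS is ≤1.5 kb —
measured edge-to-TSS by default, consistent with "more than 1.5 kb away";
midpoint mode is available. Regions on chromosomes with no annotated TSS
are not dropped: they get infinite distance, an enhancer label and a
warning.

Merged gene lists take the **union** of shape-based and differential-based
evidence: broader+higher genes = genes of broader+higher pairs ∪ genes of
enriched regions (narrower+lower symmetric with depleted). Genes reached by
several peaks can appear in more than one list; they are reported in
`multi_list_genes` so double-driving genes can be audited rather than
silently deduplicated.

Expression integration applies a strict more-than-two-fold rule (`> 2`,
`< 0.5`; a gene exactly at 2.0 is unchanged), set intersections report
sizes and overlap, the promoter co-mark cross-tab splits gained-mark genes
into gained / already-positive / negative, and term enrichment is a plain
hypergeometric upper tail against a user-supplied universe and GMT map —
deliberately not an ontology-aware tool; the universe is an explicit
required input because enrichment is meaningless without one.

## The synthetic data generator

`synthetic_config()` defaults encode the study conditions the pipeline is
designed around: partition proportions 0.84 / 0.07 / 0.087 (renormalized to
sum to one, a shift under 0.3 points), shape proportions 0.021 / 0.030
among shared sites, expression proportions 0.043 / 0.032, four replicates
per condition, Poisson count noise. Geometry is a fixed grid of 10 kb slots
(one site per slot), which guarantees non-overlapping peaks and TSS spacing
well over twice the promoter flank; genes are strand-balanced with one TSS
each. Planted effects keep margins from the classification thresholds —
width deltas at least 500 bp beyond (or below) 1.5 kb, height ratios at
least 2.5 (or ≤ 1/2.5) for shifted sites and inside [1/1.5, 1.5] for
unchanged ones, fold changes at least 2.5 (or ≤ 1/2.5) for planted
up/down genes — so noise-free recovery of the truth table is exact and
boundary semantics are tested separately with handcrafted fixtures.

Expected fragment counts are height × width / 100 bp (one fragment per
100 bp per unit height) times a depth factor; coverage is a rectangular
plateau per region whose mass equals count × 100 bp, keeping counts and
tracks consistent and making mean/max height analytically checkable. Each
generator stage draws from its own RNG stream derived from the master seed,
so partial config changes do not perturb unrelated stages, and identical
configs produce byte-identical outputs.

What the generator does *not* emulate: irregular peak shapes, overlapping
or nested peaks, fragment-length and GC bias, input/background structure,
mappability gaps, replicate-specific efficiency differences, and
correlation between occupancy and expression changes (peak categories and
DE directions are planted independently). Passing tests on synthetic data
therefore demonstrate algorithmic correctness — recovery of a known truth
under controlled noise — not biological validity on real nerve chromatin.

One visible consequence of realistic mechanics: because the mutant condition
carries slightly more total signal mass (more mutant-only sites, heavier
broader+higher sites), 1× normalization scales mutant coverage down a little
relative to control, biasing measured height ratios low. Under default noise
this inflates the narrower+lower fraction by a few tenths of a percentage
point at 5000 sites — visible in the acceptance numbers and well inside the
±1.5-point recovery bound, but worth knowing when reading close comparisons.

## Problem sizes and runtimes

The shipped checks use 2000 sites for noise-free truth recovery, 5000 sites
for planted-fraction recovery, 2000 regions × 4 vs 4 for null calibration,
500 × 500 intervals for the brute-force overlap oracle and universes ≤ 25
for exhaustive hypergeometric enumeration — sizes chosen so the whole suite
runs in well under a minute while keeping binomial sampling error far below
the tolerances tested. The acceptance script re-simulates everything from
its `--seed` in a few seconds.

## Known limitations

* The permutation test is conservative at small replicate numbers (see the
  calibration ceiling above) and has no dispersion model; with many
  replicates a count-model test will be more powerful.
* Pairing is one-to-one; a peak that splits into two in the other condition
  contributes one pair plus one condition-specific peak rather than a
  one-to-many match.
* Height summaries are replicate-averaged; "reproducibly" shifted in the
  per-replicate sense is not implemented.
* bigWig input requires rtracklayer; bedGraph is the native path.
* The naive threshold peak caller exists only as plumbing for end-to-end
  synthetic runs and is not a substitute for a model-based caller on real
  data.
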