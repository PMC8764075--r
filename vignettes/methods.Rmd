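---
title: "Methods: multi-scale chromatin architecture across a four-stage trajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale chromatin architecture across a four-stage trajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

HiCOntogeny analyses binned cis Hi-C contact matrices together with
histone-modification and transcription-factor (TF) ChIP peak sets and
single-cell expression across an ordered series of four cell stages, the
design used to follow hematopoietic stem cell (HSC) ontogeny through the
endothelial-to-hematopoietic transition: early arterial endothelial cells
(eAEC), hemogenic endothelial cells (HEC), pre-HSCs and long-term HSCs
(LT-HSC). The package covers three structural scales — A/B compartments at
100 kb, TAD boundaries and intra-TAD connectivity at 40 kb, and chromatin
loops at 10 kb — and integrates them with regulatory annotation and
stage-trend statistics. A synthetic-data generator with a serialisable
planted truth provides end-to-end parameter-recovery validation.

# Contact-matrix model and normalization

A `ContactMatrix` holds symmetric non-negative binned cis counts for one
chromosome with a 0-based half-open bin table (bin id = floor(start /
bin size)). Three normalizations are supported:

* **Knight-Ruiz balancing** (`krBalance`): the Newton-type inner-outer
  iteration with conjugate-gradient inner solves, run after dropping bins
  whose marginal falls below a configurable quantile of the positive
  marginals (default 5%; zero marginals always dropped). Convergence is
  declared when every unfiltered row of `diag(w) M diag(w)` sums to 1
  within `tol` (default 1e-6); non-convergence raises an error naming the
  chromosome. Filtered bins carry `NA` weights.
* **Library scaling** (`normalizeToSmallest`): each library is multiplied
  by (smallest total)/(its total), so all libraries match the shallowest
  one exactly and counts-per-million comparisons are depth-free.
* **Observed/expected** (`observedOverExpected`): the decay expectation is
  the per-chromosome mean contact at each separation (NA-aware); each pixel
  is divided by the expectation at its distance. When the curve is computed
  from the same matrix, the mean obs/exp at every distance is exactly 1,
  and the transform is invariant to global count scaling. The default uses
  balanced values when weights are present, with a flag to use raw counts;
  the choice is recorded by the caller because published pipelines do not
  always state it.

# Compartments and flip classification

Compartments are called at 100 kb from the sign of the leading eigenvector
of the Pearson correlation matrix of obs/exp contacts, per chromosome.
The sign is oriented so that A-labelled bins have the higher mean gene
density; a per-bin mean-expression vector may be supplied as a secondary
orientation criterion, used only when gene density does not discriminate
(off by default). Degenerate inputs — constant obs/exp, all-NA rows, a
near-zero-variance correlation matrix — yield an all-NA track rather than
arbitrary signs.

Across the four stages, each bin's label sequence is classified as
stable-A, stable-B, A-to-B, B-to-A, or transient. Changes in one direction
only are directional flips (net first-to-last direction); any sequence in
which both an A-to-B and a B-to-A change occur is transient, including
sequences that return to their starting label (B,B,A,B is transient).
Bins NA at any stage are excluded from the denominator. The flip fraction
is (A-to-B + B-to-A + transient)/classified, and the five categories always
partition the classified bins.

# TAD boundaries and domain scores

The insulation score of bin *b* is the mean distance-stratified z-score of
the `windowBins` x `windowBins` block of contacts crossing *b* (left flank
x right flank); boundary strength is its negative. We use a single-scale
window of 5 bins (200 kb at 40 kb) rather than a multi-scale consensus:
the single-scale statistic is fully specified and testable, and the window
is exposed in the configuration. Because z-scores are per-separation, the
profile is invariant to global count scaling. Boundaries are prominence-
filtered local minima; at a sharp two-block junction the crossing window is
tied between the last upstream and first downstream bin, so boundary
positions are meaningful to within one bin. Cross-stage boundary
variability is ranked by the standard deviation of raw strengths (row
scaling is reserved for display and clustering), with ties broken by
genomic coordinate.

The **domain score** of a TAD is the ratio of intra-TAD pairs (both ends
inside) to all TAD-associated pairs. The denominator is read as "pairs
with at least one end in the TAD, cis only"; the alternative reading (all
cis pairs on the chromosome) is available behind a flag because the
published phrase is ambiguous. Normalization proceeds in three steps:
divide by the mean score of 1000 random same-size placements on the same
chromosome (uniform over valid start bins, with replacement, placements
shared across libraries for a fixed seed); subtract the per-library mean
over all TADs; quantile-normalize across libraries (mean-of-sorted-values
reference, ties averaged). On a translation-invariant pure-decay matrix
the ratio is ~1 and centered scores sit at 0, which the tests verify.
Note that quantile normalization removes library-wide shifts by design: a
stage trend planted in *every* TAD is normalized away, so trend recovery
is always assessed for a planted subset against a background of unchanged
TADs — which is also how top-variable-TAD analyses are used in practice.

Cross-stage selection requires replicates: per-TAD one-way ANOVA across
stages, Benjamini-Hochberg adjustment, an FDR cutoff (default 0.001), then
ranking by the variance of stage means, keeping the top k (default 1000,
ties by coordinate). Stage-series heatmap clustering uses row z-scaling
and Ward (`ward.D2`) hierarchical clustering — deterministic and
permutation-equivariant. Adjacent-stage log2 fold changes use a 1e-6
pseudocount, after shifting a series containing non-positive values
(centered domain scores can be negative) so its minimum is at the
pseudocount.

# Loop detection and quantification

Loop detection at 10 kb is a donut-style local-enrichment test: a pixel in
the separation window (50 kb-2 Mb) is a candidate when its raw count
exceeds `foldMin` (1.5) times the donut background — the neighborhood mean
over an 11x11 window excluding the pixel's own row and column — and at
least 2; candidates are tested against a Poisson upper tail with the donut
mean as rate, BH-corrected across candidates at `pMax` (0.05), and
adjacent significant pixels (8-neighborhood) merge into one loop keeping
the maximum-enrichment pixel. The exact candidate filtering of published
loop callers is not re-derived; this fully specified test plays the same
role in the pipeline and its false-call rate and recall are measured
directly on synthetic data. The Poisson rate is floored at a small value
(0.01) to guard near-empty donuts at extreme separations.

Loop strength is quantified two ways: CPM (raw pixel count x 1e6 / total
cis pairs) and the aggregate obs/exp (APA) over anchor pairs. The APA
center enrichment divides the center of the mean window by the mean of its
four 3x3 corner blocks; single corner pixels are too noisy to normalize
against. Distance-matched random anchor pairs (same separation
distribution, fixed seed) provide the control. Region-pair quantification
averages obs/exp over all bin pairs between two regions (flagged if the
regions overlap) and supports a sliding series of windows relative to a
fixed region, as used for promoter-centred loop-strength scans at 5 kb.

# Regulatory annotation and integration

Promoters are TSS +/- 5 kb windows; enhancers are H3K27ac peaks with any
promoter-window overlap removed whole (a peak straddling the window edge
by 1 bp is dropped entirely — the simplest reading of "excluding" —
rather than trimmed). Anchor labels use promoter precedence: an anchor
overlapping both a promoter and an enhancer is P, keeping E-E/E-P/P-P/other
a partition. TF engagement of an E-P interaction requires a TF peak on at
least one anchor (the published definition); a stricter variant requiring
occupancy on the anchors' E/P elements is behind a flag. Subtypes record
whether occupancy falls on the promoter anchor, the enhancer anchor, or
both. Genes are assigned to an interaction when the TSS-to-anchor distance
is at most 20 kb (TSS, not gene body: the distance convention is not fixed
by the annotation tools the field uses, so the simpler one is taken).

ChIP signal on regions is peak-restricted and per-million normalized:
coverage is summed only over the intersection of the region with the
mark's peaks, times 1e6 over the library size — additive over disjoint
regions and homogeneous in coverage scaling. Boundary metaprofiles average
this signal in 101 offset bins of 10 kb across +/- 500 kb windows around
boundary centers, skipping (and counting) boundaries too close to an edge.

Expression trends on the log2(TPM/10+1) scale use the three adjacent-stage
deltas with a dead-band of 0.25 (no threshold is published; 0.25 on the
log2 scale is a quarter-doubling, comfortably above scRNA-seq stage-mean
noise at the cell numbers involved, and it is exposed in the
configuration): all within the band is flat, positive-only is up,
negative-only is down, both directions is transient.

The Wilcoxon rank-sum test is implemented with exact enumeration for
combined n <= 12 (average ranks for ties; two-sided permutation
probability) and the normal approximation with tie and continuity
correction otherwise; it is cross-checked in the tests against both a
brute-force permutation oracle and `stats::wilcox.test`. ANOVA is the
vectorized one-way F-test with BH adjustment applied within each feature
family separately.

# The synthetic generator

The generator is first-class, tested code. It emulates the four-stage
design: a genome frame with uniformly placed genes; per-stage A/B labels
on 100 kb blocks (block lengths 4-12 bins, labelled A where gene density
is high so the orientation convention holds on planted data); a TAD
partition on a 200 kb grid with per-stage intra-TAD enrichment factors
(flat 1.8-2.6, increasing 1.5-1.8 to 2.6-3.0, decreasing the reverse — at
least ~1.5x contrast at every stage, i.e. boundaries exist throughout with
varying strength); loops between enhancer/promoter elements with
trajectory-classed multipliers (increasing 1/2/3.5/5, decreasing the
reverse, ephemeral 1/4/4/1, stable 3/3/3/3); per-stage mark intensities
with stage-onset enhancers; and TF occupancy arranged so that an exact
fraction (default 0.40) of enhancer-promoter loops is engaged.

Contacts are Poisson draws around a multiplicative model on a power-law
decay baseline (default exponent 1.0): same-compartment 100 kb pairs x c,
different x 1/c (default c = 1.5), intra-TAD pairs x the TAD's stage
factor, loop pixels x the loop multiplier; the expected total equals the
requested depth. Two deliberate idealizations matter for interpretation:

* Compartment modulation applies only beyond 2 Mb separation.
  Compartmentalization is a long-range plaid; applying it at short range
  would plant spurious insulation dips at every 100 kb block edge, which
  no real dataset shows at that density.
* Loop anchor bins are exclusive across loops and planted loop pixels are
  Chebyshev-separated by >= 3 bins, so detected loops map one-to-one onto
  planted loops and TF occupancy on one loop cannot engage another. Real
  loop lists contain shared anchors; classification exactness on the
  synthetic truth therefore validates the bookkeeping, not robustness to
  anchor sharing.

Expression responds to increasing/decreasing loops with a one-stage lag
(the multiplier at stage t is the loop's at t-1) for genes within 20 kb of
an anchor, encoding a delayed transcriptional response as a testable
planted effect. Cells per stage default to 42/33/50/16, matching the
single-cell sample sizes typical of these sorted populations. The
generator does not emulate trans contacts, read-level data, copy-number or
mappability artifacts, nor continuous (non-block) compartment strength; a
pass on synthetic data shows the statistics recover what they are defined
to recover under this noise model, not that they are robust to artifacts
the model omits.

All truth structures serialize to JSON and round-trip exactly, so every
planted parameter is recoverable from the truth file alone.

# Problem sizes and determinism

The validation suite uses desk-scale problems chosen to keep each
statistic in its operating regime: 20 Mb chromosomes at 40 kb (500 bins)
with 1e6 pairs per stage for boundary and domain-score work; 50 Mb at
100 kb (500 bins) with 1e6 pairs for compartment flips; 10 Mb at 10 kb
(1000 bins) with 2e6 pairs for loop-null calibration and 5e6 for recall —
about the per-length coverage at which 10 kb loop calling becomes
reliable. Every stochastic entry point takes a seed, restores the caller's
RNG state, and derives child seeds from (seed, label), so a pipeline rerun
with the same configuration is bit-identical; the run manifest records the
configuration hash and seed.

# Known limitations

Single-scale insulation (no multi-scale consensus); no hierarchical or
nested TADs; no trans contacts; no sub-compartments; loop detection is a
re-specified donut test, not a reimplementation of any published caller;
boundary positions are resolved to within one bin by construction. The
cross-stage TAD comparison uses one consensus partition called on the
pooled matrix so domain scores are comparable across stages — published
analyses do not state which stage anchors the partition, and the pooled
choice avoids privileging any one stage.
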