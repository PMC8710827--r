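---
title: "Detecting, dating and phenotyping a lineage-specific WGD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, dating and phenotyping a lineage-specific WGD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grasswgd` implements the comparative-genomic inference chain used to
establish that a grass genome underwent a whole-genome duplication (WGD)
of its own after splitting from its relatives, and to ask what became of
the duplicate gene pairs under salt stress.  This vignette explains each
stage's model and assumptions, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the underlying procedures are conventionally left
unstated.  Everything quantitative asserted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Genome size from the k-mer spectrum

For reads at mean depth $c$, the depth histogram of distinct canonical
k-mers has a main peak near the effective k-mer coverage and, in a
heterozygous diploid, a secondary peak near half that depth (each allele
of a heterozygous site carries its own k-mer neighbourhood at half the
coverage).  The estimator is the classical
$$\widehat{G} = \frac{\text{total k-mer instances}}{\text{main peak depth}},$$
implemented in `estimate_genome_size()`.  Two readings of the numerator
are possible; `mode = "raw"` uses all instances (the default, since the
ratio of the published instance total to the published peak depth
reproduces the published size estimate exactly only in this mode), and
`mode = "error_filtered"` first removes instances below the error trough,
which matters when the per-base error rate is appreciable (raw totals
inflate $\widehat{G}$ by roughly $c \cdot e \cdot k$ instances per
genomic position).

Counting is canonical (a k-mer and its reverse complement are one key),
so depth tracks coverage regardless of read strand; `k` must be odd so
that no k-mer is its own reverse complement.  `call_peaks()` smooths with
a 3-bin moving average, takes the first local minimum after depth 1 as
the error trough, the argmax beyond it as the main peak, and reports a
heterozygous peak only inside $[0.4, 0.6]\times$ the main depth and above
10% of the main peak height.  The window and prominence values are not
dictated by any published procedure; they were chosen once for robustness
on low-coverage simulations and are exposed as arguments.

The generator (`simulate_kmer_histogram()`) composes the mixture
directly by default: homozygous k-mers at Poisson depths around
$c_{\mathrm{eff}} = c\,(1-e)^k\,(L-k+1)/L$, $2k$ heterozygous k-mers per
heterozygous site at $c_{\mathrm{eff}}/2$, and error k-mers at depth 1-2.
A read-level mode (synthesising a diploid genome and counting with
`count_kmers()`) exists for small genomes and agrees with the mixture on
the main peak; the mixture mode does not emulate repeat-induced
high-depth shoulders, so recovery tests on it say nothing about
repeat-rich spectra.

## Homology, collinearity and the dotplot argument

`find_homologs()` performs the all-vs-all protein comparison behind a
synteny analysis: a shared exact 5-residue word prefilters candidate
pairs (bounding the quadratic cost), local alignment (BLOSUM62, gap open
11, extend 1) scores survivors, bit scores follow the Karlin-Altschul
form with the subject proteome as the database, and hits are kept at
E-value $\le 10^{-5}$ with at least half of the shorter protein aligned.
Ranks per query are assigned by descending score with lexicographic
tie-break, a deterministic-output contract.

`chain_anchors()` re-implements collinear chaining as explicit dynamic
programming rather than binding to an external collinearity tool, so the
block definition is fully testable: an anchor extends a chain iff the
gene-order gap on both axes is at most `max_gap` (default 50 genes) and
the second-axis direction matches the chain's orientation; both
orientations are searched, maximal chains are peeled off greedily, and
chains below `min_block_pairs` (default 5, the conventional minimum) are
dropped.  On instances small enough to enumerate, the chained block
equals the exhaustive optimum (property-tested).  Tandem-array collapsing
is not performed; the simulator plants no tandem duplicates, and
intra-genome runs instead exclude self-hits and anchors within 5
positions of the self-diagonal.

The dotplot argument for an extra WGD reads multiplicities off the
classified blocks.  `classify_blocks()` labels a block orthologous iff
more than half its anchors are rank-1 hits of the reference-side gene
(exact ties resolve by mean rank against blocks covering the same
reference span); `infer_multiplicity()` merges orthologous blocks into
regions per reference chromosome and reports the modal number of
distinct focal locations.  One lineage-specific WGD yields modal
multiplicity 2 — the 1:2 ortholog signature — because fractionation puts
each surviving copy in the rank-1 position wherever its sister was lost:
with per-copy survival $s$, the expected rank-1 fraction of a co-ortholog
block is $1 - s/2 > 1/2$.  This also exposes the rule's limit: with two
stacked focal WGDs the four co-ortholog blocks each expect a rank-1
fraction of $\mathrm{E}[1/S] < 1/2$, and — because no duplication
predates the speciation in that scenario — there is no outparalogous
tier for the rule to separate them from.  `infer_multiplicity()`
therefore accepts `classes = NULL` to count all collinear regions, which
is the appropriate reading in the stacked case; the default
(`"orthologous"`) is the published single-extra-WGD case.  Region
support defaults (`min_region_pairs = 10`, `merge_gap = 50`) were fixed
once so that fractionation at retention 0.5 still yields clean counts in
simulation.

## Ka/Ks and Ks-peak dating

`estimate_ks()` implements NG86 counting: per-codon synonymous site
fractions from the standard genetic code (mutations to stop codons count
as nonsynonymous), differences averaged over all minimal substitution
pathways with stop-containing pathways excluded, and Jukes-Cantor
correction $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$ with a saturation
flag when the logarithm's argument is non-positive.  The 64×64
pathway-average tables are verified against an independently coded
exhaustive enumeration over all 61×61 sense-codon pairs.  NG86 was
chosen over a YN-class estimator because it is exactly oracle-checkable;
at the divergence depths relevant here the peak-location difference
between the two estimator families is smaller than the mixture component
spread, and the method is recorded in every output row.  Alignments come
from `backtranslate_alignment()` (codon-faithful expansion of a protein
alignment, gap columns dropped for counting) with a 30-codon floor that
can be relaxed for toy examples.

Peak analysis operates on block-average Ks (`block_ks_distribution()`,
window $(0, 2]$, at least 3 usable pairs per block): averaging within
blocks suppresses per-pair estimation noise and makes the duplication
events, not the pairs, the sampling unit.  `detect_ks_peaks()` fits
Gaussian mixtures to $\log K_s$ (Ks is right-skewed and multiplicative)
for 1-4 components, selects by BIC, and back-transforms component means;
a Silverman-bandwidth KDE mode finder cross-checks the result and flags
relative disagreement above 25%.  Ages follow by proportional
calibration, `date_event()`: age $= 96\,\mathrm{Ma} \times K_s / 0.6$
by default, anchored on the grass-wide duplication.  Both anchor values
are configuration, not constants: proportionality at this anchor maps a
0.15 peak to 24 Ma, and no single linear rate reproduces every published
grass dating simultaneously, so the package exposes the calibration and
does not tune it.

## Ancestral-karyotype painting

`paint_karyotype()` takes an external gene-to-protochromosome map (the
ancestral karyotype is an input, never inferred), votes over sliding
gene-order windows (width 10, ties lexicographic), merges same-label
runs, absorbs segments under 5 genes into their larger neighbour, and
flags a chromosome as fused iff two or more labels survive.  Planted
end-to-end fusions are recovered exactly when segments are comfortably
larger than the absorption floor; the absorption step means mosaics of
very short alternating segments are deliberately read as noise, not as
fusions.

## Differential expression and duplicate-pair fates

The DEG stage is a self-contained negative-binomial Wald test in the
DESeq mould, re-implemented rather than wrapped so that every step is
inspectable and testable against planted truth: median-of-ratios size
factors; per-gene method-of-moments dispersion on normalised counts,
shrunk in log space toward an $a_0 + a_1/\mu$ trend with weight
$df/(df+4)$; a delta-method Wald z-test on the log2 fold change against
the same-tissue 0 h control; BH correction within each (tissue, time)
contrast, excluding all-zero genes from the family.  A gene is a DEG iff
$|\log_2 FC| \ge 1$ and FDR $< 0.05$.  The exact dispersion-shrinkage
weights differ from any published implementation and are documented
here; on planted simulations the test controls type-I error under the
null and detects 4-fold effects at $\mu = 100$, $\alpha = 0.1$, 4 vs 4
replicates with high power, and its calls agree closely with an
independent NB implementation on the same counts.

`pair_paralogs()` assembles the two-copies-vs-one-reference-copy
configuration: collinear partners inside an intra-focal block whose mean
Ks falls below the midpoint of the two youngest focal peaks (i.e.
attributable to the lineage-specific event), both anchored to the same
reference gene inside orthologous-classified blocks.  Membership in an
orthologous block — not per-query rank 1 — is the anchoring criterion,
since the two co-orthologs of a reference gene necessarily split ranks 1
and 2 between them.  Reference genes with three or more mapped focal
copies are excluded.

`classify_fate()` collapses time points by taking, per copy, the union
of (tissue, direction) DEG signatures — the only lossless collapse — and
assigns: pattern I, identical signatures (redundancy); II, different
tissue sets with compatible directions; III, same tissue sets with a
direction conflict; IV, both a tissue difference and a direction
conflict.  A copy that is up at 6 h and down at 24 h in one tissue
carries both directions and can legitimately push a pair into III/IV;
this is reported, not suppressed.  `summarize_fate()` tabulates
categories (neither/one/both DE) and patterns with two-decimal
round-half-up percentages (`percent()`), the rounding convention that
reproduces printed ratio tables.

## The generator as the study's stand-in

`simulate_wgd_genome()` evolves every gene down an explicit tree: a
proto genome, an optional shared ancient WGD (both lineages), the
speciation, and one or more focal-specific WGDs, with branch lengths
chosen so that each pair class hits its target Ks in expectation
(defaults: shared 0.6, speciation 0.45, specific 0.15 — the divergence
depths characteristic of the system this package models).  Coding
sequences evolve by Poisson placement of point mutations (uniform
positions, uniform alternative bases), accepting synonymous changes
always, nonsynonymous with probability $\omega$ (default 0.2), and
stop-creating changes never; accepted-event densities then equal
$d_S$ and $\omega\,d_S$ on the NG86 site scale while multiple hits
accrue naturally, which is what makes the estimator-consistency tests
meaningful.  Fractionation deletes each WGD-derived copy independently
with survival `retention_prob` (default 0.7) — unbiased, since there is
no evidence for biased loss to emulate — and chromosome fusions and
Poisson inversions rearrange the focal genome.  CDS length is fixed at
150 codons by default: long enough for stable NG86 estimates and
alignment ranking, short enough for desk-scale runs.

What the generator does **not** emulate: tandem duplication, gene
conversion between paralogs, indel evolution, biased fractionation,
expression correlation between neighbours, and repeat content.  Tests
passing on this generator therefore demonstrate correctness of the
inference machinery under the stated model, not robustness to every
property of real genomes.

Expression counts (`simulate_counts()`) are NB draws around log-normal
baselines with planted (tissue, time) effects; duplicate pairs are
allocated deterministically across the no/one/both-DE categories and,
within both-DE pairs, across patterns I-IV (defaults approximate the
proportions this class of study reports, roughly 79/15/6 and 64/27/2/7),
then assigned randomly to pairs, so planted proportions are exact and
recovery can be scored within sampling error.  All generators are
deterministic given their seed (byte-identity is tested).

## Problem sizes and numerical choices

The suite runs at deliberately modest sizes chosen once as adequate for
each property: multiplicity at 5 reference chromosomes × 200 genes
(retention 0.7), Ks-peak recovery at 200 + 200 blocks of 5 pairs × 300
codons, estimator consistency at 250 pairs per depth, DEG calibration at
2000 genes × 3 seeds, fate recovery at 600-800 pairs.  Degenerate inputs
are handled explicitly: identical Ks values collapse to one component
with a floored spread; empty chromosomes during fractionation trigger
bounded regeneration with a warning; all-zero expression samples warn
and return zero TPM columns; zero-control genes in `fold_regulation()`
survive via a 0.5 pseudo-count on both group means.

## Interface

The package is function-first: the exported functions compose the
pipeline, the test suite demonstrates every composition, and
`scripts/acceptance.R` re-runs the headline computation from scratch.
No shell entry point is shipped; an analysis of this shape is driven
from R.

## Known limitations

Only NG86 is implemented for Ka/Ks (a YN-class option is a natural
extension); block significance is by size only, with no statistical test
on blocks; the majority-rank classifier presumes at most one extra WGD
atop the shared one (see above for the stacked-event reading); painting
trusts the input ancestral map and cannot detect fusions between regions
of identical ancestral origin; and proportional Ks dating inherits every
caveat of a single linear synonymous clock.
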