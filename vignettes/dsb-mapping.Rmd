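---
title: "Mapping off-target DSBs from strand-oriented ChIP-Seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping off-target DSBs from strand-oriented ChIP-Seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dsbmapr` identifies off-target double-strand breaks (DSBs) induced by
activation-induced cytidine deaminase (AID) from Nbs1 ChIP-Seq, classifies
them by strand signature, and characterises the tandem-repeat context —
WGCW hotspot arrays and CA (Z-DNA-capable) microsatellites — that makes a
genomic site break-prone. This vignette explains the models, the tunable
parameters, and the design decisions, and states exactly what the bundled
synthetic data do and do not establish.

## The read model at a break

Sonication fragments the genome; ChIP for a DSB-bound protein enriches
fragments whose end *is* the break. Sequencing from fragment 5' ends then
yields a characteristic pattern: the left fragment contributes minus-strand
tags immediately left of the break, the right fragment plus-strand tags
immediately right, both piling at the break, while sonication-end tags
scatter a fragment length away. A transcription-factor footprint gives the
mirror image (plus tags left, minus tags right). Three consequences drive
the pipeline:

* shifting each 5' end half a fragment length toward the fragment midpoint
  concentrates both strands of a two-ended break into one narrow pileup —
  the counting used by the peak caller;
* a break with only one detectable end (a replication fork running into a
  nick) yields tags on a single strand — the one-ended signature;
* the order of the per-strand 5'-end centroids distinguishes breaks from
  transcription-factor footprints.

## Coordinates and input

All internal coordinates are 0-based half-open (BED-native); 1-based
display is formatting only. A *tag* is the 5'-end position of one aligned
read: the BED start on the plus strand, end − 1 on the minus strand. Tag
identity for duplicate capping is (chromosome, 5' position, strand);
`deduplicate()` keeps the first `max_per_position` occurrences. A cap of 1
removes all duplicates (appropriate for shallow libraries); "retain two
duplicates" is read as cap = 3 — the original plus two — with the stricter
reading selectable, since the phrase is genuinely ambiguous.

## Fragment-length estimation

`estimate_fragment_length()` maximises the Pearson correlation between the
plus-strand 5'-end density and the minus-strand density shifted left by
*d*, over *d* ∈ [read length, 500]. The correlation is computed exactly but
sparsely — the cross-covariance at shift *d* equals the number of
(plus, minus) tag pairs at distance *d*, so tabulating pair differences
replaces dense megabase vectors — restricted to chromosomes with ≥ 10,000
tags, and smoothed with a triangular kernel (half-width 10 bp) that
suppresses 1-bp shot noise without displacing isolated peaks. Ties break to
the smallest shift, so degenerate inputs (identical strand densities) fall
to the read-length lower bound. A control ChIP usually lacks enriched sites
to anchor the peak, and sonication is common to both samples, so
`run_pipeline()` shares the WT estimate with the control.

## Peak calling and the tier filter

Candidates: a 500-bp window slides at 1-bp steps over the shifted 5' ends;
local maxima are accepted greedily by descending count with centers at
least one window width apart (ties to the leftmost coordinate, then
lexicographic chromosome order); windows need ≥ `tag_floor` WT tags
(default 10, deliberately below the lowest filter tier so the tier filter
binds) and a fold change ≥ 2.0 over the control count scaled to the WT
library size. A pseudocount of 0.5 on scaled control counts and background
densities avoids divisions by zero; it is configurable, as the choice is
conventional. The local-background ratio compares window density with the
surrounding 10-kb span (window excluded, span clamped and renormalised at
chromosome edges).

The tier filter encodes the empirical retention rules on the *raw* tag
count of the called window — tag counts in the rules are raw capped counts,
not library-normalised, because the thresholds were set per experiment.
Two profiles ship both as code (`tier_profile("exp1")`, `"exp2"`) and as
editable TSVs under `inst/extdata/`. Survivors are extended 1,000 bp each
side of the window center (clamped at chromosome edges by shortening, never
shifting — matching the slight deficit of mean site length below 2,000 bp).

AID-independent sites use the no-control path: candidates pass on local
background alone (ratio ≥ 4.0), then must have a normalised WT:control
ratio ≤ 1.4 over the *extended* interval. Using the extended interval
avoids a subtle bias: the called window is placed at the WT argmax, which
inflates the WT count relative to a control counted in the same fixed
window.

## Strand-bias and orientation classification

`strand_bias()` counts per-strand 5' ends over the 2-kb extended interval
(selectable). The operative one-endedness threshold is |log₂(plus/minus)| >
1.5; the "2.8-fold" phrasing is treated as a rounding of 2^1.5 = 2.83, so
a 28:10 site is *not* one-ended. With one empty strand the ratio is an
infinite sentinel and the call requires ≥ `min_total` (10, invented) tags
on the populated strand; two empty strands are indeterminate, never an
error.

`orientation_signature()` compares per-strand 5'-end centroids:
`dsb_like` when the minus centroid sits left of the plus centroid by at
least `gap_min` (20 bp, an invented noise guard), `tf_like` for the mirror,
`indeterminate` below 5 tags per strand or inside the guard. Centroids are
taken over the 500-bp called window by default rather than the 2-kb
extension: with realistic background rates, a handful of uniform flanking
tags acquires enough leverage over a 2-kb mean to flip the centroid order
at roughly one site in seven, while the called window is dominated by the
break-proximal pileup.

## Tandem repeats and motif density

`find_tandem_repeats()` is an indel-free repeat finder: position *i* scores
+2 if it matches the base one period back and −7 otherwise (N always
mismatches); maximal-scoring segments (recursive Kadane decomposition,
fully vectorised) above the minimum score become repeats spanning
`[segment_start − p, segment_end)`; overlaps across periods resolve to the
highest score, ties to the smallest period — so a (CA)ₙ array is reported
at period 2, not 4. Restricting to periods ≤ 12 and dropping indel states
is deliberate: the repeat classes of interest here are near-pure pentamer
and dinucleotide microsatellites, for which a pure array of motif length
*p* and total length *L* scores exactly 2(*L* − *p*). The suite proves the
implementation equivalent to an exhaustive (start, end, period) enumeration
on short sequences.

Classification: CA if ≥ 90% of dinucleotide steps are CA/AC/TG/GT ("core
repeat motif" is not further specified; a consensus-based rule would behave
the same on near-pure arrays); otherwise WGCW if the repeat holds ≥ 2.0
WGCW motifs per 100 bp; CA takes precedence, so no repeat is both. WGCW
scanning uses IUPAC matching with overlaps on the plus strand only — the
motif is self-complementary as a degenerate pattern, which the suite also
verifies. Site summaries run two passes (minimum score 100 for the WGCW
classification, 60 for CA, the parameterisation under which the thresholds
were set) and flag sites at ≥ 400 summed bp of WGCW-class repeats and
≥ 100 bp of CA-class repeats. The summed-length reading of "≥ 400 bp in
length within called site" was chosen over single-longest-tract because
merged sites can interleave repeat tracts; the alternative is one `dplyr`
filter away on the per-repeat table.

`genome_background()` draws random intervals matched to a site set's length
and chromosome distribution (uniform starts, redraw when an interval
exceeds its chromosome) and summarises them identically — the null for the
repeat-content percentages.

## Interval statistics

Merging uses ≥ 1 bp overlap (no slop, configurable) with per-source
provenance; reproducible sites are merged intervals to which both
experiments contributed, which is also why they are longer on average than
single-experiment sites. The permutation test redraws the target set
(`randomize = "query"` selectable) preserving each interval's length and
chromosome with uniform starts, and reports the +1-corrected empirical
p-value — never zero, and "< 0.001" is the floor at 1,000 trials — plus
enrichment over the null mean.

## The synthetic-data generator

`simulation_config()` defines the study conditions: 3 × 5 Mb chromosomes at
GC 0.42; 100 two-ended AID-dependent sites, 10 one-ended, 20
AID-independent and 10 TF-pattern sites at λ = 30 expected site reads;
background 0.002 tags/bp per library (so a 3:1 library-size imbalance is
not modelled, but the scaling path is exercised by the WT/control
difference that does arise); fragment length 200 ± 50 bp; 36-bp reads.
Thirty of the two-ended sites carry a 450-bp CAGCA array (the most common
off-target pentamer; 20 WGCW motifs per 100 bp, the same order as the Sμ
switch region) and twenty a 150-bp CA array, with ten standalone arrays of
each class elsewhere and 3% per-base array mutations.

Model choices worth knowing:

* Tags are emitted directly as aligned genomic 5' ends — alignment is out
  of scope, so no sequencing-error model.
* Break-end 5' ends carry an end-processing offset, |N(60, 20)| bp away
  from the break (minus left, plus right), plus 5-bp jitter. Break ends
  in vivo are resected/processed over tens of bases; the offset reproduces
  the minus-left/plus-right orientation signature at a scale the centroid
  classifier can read, while keeping both strands inside one called window.
* Sonication-end tags are emitted at 0.05 per break-end tag, a fragment
  length from the *processed* end (keeping the cross-correlation peak at
  the true fragment length). The low rate reflects that Nbs1 ChIP enriches
  break-proximal ends — visible in real data as one-ended sites with tags
  on a single strand only.
* AID-independent sites draw one intensity per site shared by both
  libraries (they are the same breaks in both genotypes); placement noise
  and background stay library-specific. With fully independent draws, a
  site whose control draw lands low would spuriously exceed the 1.4 ratio
  cap, making "every planted shared site is recovered" unattainable as a
  property rather than as a statistic.
* Two-ended site reads split per side as independent Poisson(λ/2) by
  default; a Binomial split of a Poisson total is selectable where exact
  totals matter.

What passing tests on these data show — and what they do not: the
simulator emulates the statistical *structure* the pipeline assumes
(orientation signature, strand-specific pileups, shared vs WT-only sites,
planted repeat context) on an i.i.d. background. Real genomes have
non-uniform mappability, copy-number structure, chromatin-biased ChIP
efficiency and repeat families the generator does not model, so recovery
rates here validate the machinery, not expected performance on real
libraries.

## Numerical and degenerate-input policy

Pseudocount 0.5 wherever a control or background count is a denominator;
clamping never errors (coverage extension, interval extension, span
renormalisation); empty inputs return empty results except where the
contract demands an actionable error (no control library, too few tags for
fragment-length estimation, sequence unavailable for a named interval).
Ties break deterministically everywhere: leftmost coordinate, then
lexicographic chromosome order; smallest shift; smallest period. All
randomness flows from explicit seeds; reruns are bit-identical.

## Problem sizes used in the checks

The shipped checks run the default 15-Mb simulation end to end, 1,000
random background intervals, 1,000-trial permutation tests, 400 null
repetitions for p-value calibration, 1,000 short sequences against the
exhaustive repeat oracle and 10,000 200-mers against the motif-count
oracle — sizes chosen so the full suite completes in a few minutes on one
CPU while every stage still operates far from its small-sample edge cases.

## Known limitations

* The repeat finder is indel-free; a polymorphic microsatellite with
  insertions is reported as fragmented tracts (the summed-length site
  thresholds absorb most of this).
* No mappability or blacklist handling; on real data, collapsed repeats can
  masquerade as enriched windows.
* The AID-independent path assumes the control library is deep enough that
  a shared site's control counts are informative; with very shallow
  controls the 1.4 cap becomes noisy.
* Broad enrichment domains (kilobase-scale) are out of scope — the caller
  is a point-source caller with a fixed window.
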