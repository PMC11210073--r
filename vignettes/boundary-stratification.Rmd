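---
title: "Stratifying TAD boundaries: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying TAD boundaries: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadstrata)
library(dplyr)
```

## The boundary-level model

Topologically associating domains (TADs) nest: a large domain may contain
sub-domains, and nested domains frequently reuse one of the parent's
endpoints. `tadstrata` stratifies TAD boundaries by how heavily they are
shared. Working on the bin grid of the TAD-calling resolution (10 kb by
default), every distinct TAD endpoint coordinate defines a *boundary bin*.
For a boundary `b`:

* `left_count(b)` — the number of TADs whose end coincides with `b`
  (domains lying to the boundary's left);
* `right_count(b)` — the number of TADs whose start coincides with `b`;
* `level(b) = min(4, max(left_count, right_count))`.

A boundary used by at most one TAD on each side is level 1; a boundary
shared by, say, three TADs to its left and four to its right is level 4;
sharing counts of four or more are capped into the "4+" class. Level 0 is
*reserved*: it labels non-boundary genomic bins and the random control bins,
and `extract_boundaries()` never emits it. The per-TAD tallies balance by
construction — each TAD contributes exactly one start and one end — which
the test suite asserts as an invariant.

Two design points deserve mention. First, a boundary is *one bin*: adjacent
distinct endpoint bins are not merged, because the stratification counts
boundaries per bin and only expands spans (by ±1 bin, giving a 30 kb span at
10 kb) when comparing across boundary sets from different callers or cell
lines. Second, caller output is snapped to the grid by rounding each of
start and end to the nearest multiple of the resolution, with exact
half-bin ties rounding down; TADs shorter than one bin after snapping are a
validation error rather than silently dropped.

## TFBS-clustered regions (TFCRs)

Transcription-factor binding sites cluster; `tadstrata` summarizes that
clustering with a Gaussian kernel density over TFBS midpoints. The kernel is
deliberately **unnormalized**: a hit at distance `d` from an evaluation
point contributes `exp(-d^2 / (2 * 300^2))`, so each contribution lies in
(0, 1] regardless of how many hits exist. This makes the rule "a hit
contributes to a peak if its contribution is at least 0.1" an absolute
threshold (radius `300 * sqrt(2 * log(10))`, about 644 bp); under a
normalized density the same rule would depend on the genome-wide hit count.

Every strict local maximum of the density profile is a TFCR; plateaus of
exactly equal density resolve to their leftmost grid point so results are
deterministic and input-order invariant. The profile is evaluated on a 10 bp
grid (configurable) restricted to within 4 bandwidths of any hit; the test
suite checks the gridded profile against a full per-bp brute-force summation
to 1e-9. A TFCR's *window* is its peak padded by the maximum contributor
distance plus half a bandwidth (150 bp) on each side; windows of adjacent
TFCRs may overlap and are not merged.

*Complexity* measures how many distinct transcription-factor families
contribute, weighted by proximity: contributions are collapsed per family by
taking the family's maximum, then summed over families. Collapsing prevents
motif redundancy within one family from inflating complexity; a cluster of
`k` families sitting within 100 bp of the peak scores within half a unit of
`k`. TFCRs are ranked by complexity and cut into ten equal-count classes
TC0–TC9 (ties broken by genomic position, class sizes differing by at most
one), with TC9 the most complex decile. Positional annotation is a
three-class rule — promoter within ±1 kb of a TSS, else genic inside a
strand-aware gene body, else intergenic.

The precursor method's exact complexity formula is not published alongside
the clustering description, so the family-collapsed contribution sum here is
this package's own concrete reading of "quantity and proximity of the
contributing TFBS"; likewise "strength" is recorded both as the density
value at the peak and as the sum of above-threshold contributions
(`contrib_sum`), since either reading is defensible.

## Enrichment machinery

All interval overlap work runs through GenomicRanges; the enrichment test
itself is computed exactly. `fisher_exact()` enumerates the hypergeometric
support conditional on the 2×2 margins and sums the point probabilities not
exceeding the observed one (with a 1e-12 relative tolerance for
floating-point ties) — the standard two-sided point-probability rule. The
reported effect size is the sample odds ratio `(a*d)/(b*c)` (infinite when
only the denominator is empty), not the conditional MLE, so it matches the
planted odds ratios of the simulator directly. `stats::fisher.test` serves
as an independent cross-check in the tests, never as the implementation.
P-values are reported raw, per comparison; `adjust_enrichments()` offers
Benjamini–Hochberg when a correction is wanted, off by default.

The background stratum for boundary enrichment is the *level-0 control*:
as many resolution-wide bins as there are boundaries, sampled uniformly
without replacement from non-boundary bins under an explicit seed. Boundary
spans for DSB overlap default to the core bin (`pad_bins = 0`); the ±1-bin
expansion is reserved for cross-set comparisons (consensus across reference
callers, conservation across cell lines), where both sides are expanded
symmetrically. Whether the original overlap-fraction figures used padded or
core spans is not stated in their methods; core is the default here and the
pad is a parameter.

Genome-wide classification tiles every chromosome at the TAD-calling
resolution. Accessibility per bin is the coverage-weighted signal mass
(value × covered bp summed over bedGraph records); bins with exactly zero
mass form category 0 and the positive bins are split into genome-wide
equal-count tertiles (categories 1–3). "Incrementally homogenized" could
also be read as equal-width signal intervals; equal-count was chosen because
it keeps every (level × accessibility) subgroup populated and makes the
category sizes self-documenting. DSB density is the number of peak
*intersections* per bin, so a peak spanning a bin edge counts in every bin
it touches — documented double-count semantics matching "number of
overlapping peaks". Genes attach to bins by TSS; a gene's boundary level is
the maximum level among boundary bins its ±1 kb promoter overlaps (2 kb is
available via `promoter_pad`), level 0 when it overlaps none.

Cross-cell-line conservation uses the minimal reading of "appearance in the
collections": a boundary's score is the number of cell lines (its own
included) with a boundary within one bin, range 1..C for C cell lines. The
original definition lives in supplementary material that is not available;
a padded-count is the least-committed formula consistent with the text, and
the pad is a parameter should exact-bin matching be wanted.

## The synthetic-data generator

Real inputs for this analysis are multi-gigabyte Hi-C, DNase-seq and DSB
sequencing downloads. The generator replaces them with a coherent synthetic
bundle whose ground truth is known, so every stage of the pipeline is
testable offline. Its central design decision: **levels are planted
constructively, not as labels.** Top-level TADs are tiled with gaps; each
top-TAD endpoint ("anchor") draws a target sharing count L from
`boundary_share_probs` and receives L−1 extra nested TADs stacked on that
endpoint. The realized level is whatever `extract_boundaries()` computes
from the resulting interval set, and the generator's own truth table is
tallied independently from the structure — self-consistency between the two
is itself a test.

One structural consequence: every stacked TAD has a second, free endpoint
strictly inside the parent, which necessarily becomes a level-1 boundary.
The realized level distribution therefore differs from the anchor
distribution in a computable way; `planted_level_probs()` returns the
expected realized proportions and the recovery tests compare histograms
against that, within a multinomial 99% envelope. Extra nesting depth
(drawn from `nesting_depth_probs`) is realized as chains of strictly-inside
children sharing no endpoints, which adds nesting without perturbing
planted anchor levels.

Features are planted per bin given the bin's level: TFBS counts are Poisson
with level-dependent rates and positions normal (sd 150 bp) around bin
centers; DSB presence is Bernoulli with
`logit(p) = logit(base_rate) + log(OR_level)`, whole-bin peaks by default so
the planted odds ratio is exact (an interval mode exists for
overlap-semantics tests); accessibility is gamma noise scaled by a level
effect with zero-inflation for level-0 bins; genes are uniform except
flagged (repair-related) genes, whose TSS is biased into boundary bins with
a configurable probability; FPKM is log-normal scaled by a level effect.
All draws descend from the single config seed, so equal configs give
byte-identical datasets.

Default values (sharing probabilities 0.60/0.22/0.11/0.07 echoing the
observed predominance of level-1/2 boundaries, base DSB rate 0.08/bin,
odds ratios 1.5–4 rising with level, accessibility and expression
multipliers rising with level, 8 genes/Mb) were fixed once as a realistic
regime for a 10 kb-binned mammalian genome and are not tuned per test.
What the generator does *not* emulate: Hi-C contact matrices, sequence
content (no FASTA), caller disagreement noise, copy-number or mappability
artifacts, and correlated placement of TFBS with accessibility beyond the
shared level effect. Passing recovery tests therefore demonstrate that the
pipeline measures what was planted — not that real chromatin obeys the
planted model.

## Numerical choices and problem sizes

* Density evaluation sums all hits within 9 bandwidths of an evaluation
  point (kernel < 3e-18 beyond), and hit blocks more than 16 bandwidths
  apart are profiled independently; both cutoffs are far below the 1e-9
  oracle tolerance.
* Exact-test enumeration is over the conditional support only, so tables
  with counts in the thousands remain instant.
* The test suite's recovery studies use genomes of 100–200 Mb at 10 kb
  resolution (10,000–20,000 bins), 200–700 top TADs, and 100 seeds per
  planted odds ratio — sizes chosen so each study finishes in seconds to a
  couple of minutes while keeping roughly 2,000 bins per comparison arm,
  enough that the sample odds ratio's median bias stays well inside 15%.
* Null calibration of both enrichment tests uses 1,000 replicates at 500
  intervals (or 1,000 genes) per arm with a 30% base rate; at these sizes
  the exact test's discreteness leaves the type-I error within 0.05 ± 0.02.

## Known limitations

* Boundary identity is bin-resolution: two callers placing the "same"
  boundary two bins apart only reconcile through the padded comparisons.
* The conservation score and the complexity formula are this package's
  explicit readings of under-specified definitions (see above); both are
  parameterized so alternative readings are small changes.
* `read_fimo()` keeps one midpoint per match; per-summit coordinates are
  not reconstructed.
* The orchestrated run (`run_full_analysis()`) analyzes one cell line per
  call; multi-cell-line conservation is composed by the user from
  `conservation_scores()`.
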