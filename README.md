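# tadstrata

Chromatin folds into topologically associating domains (TADs) that nest, and
nested domains frequently reuse a parent boundary. `tadstrata` is an R
package for asking what that *sharing* means: it stratifies TAD boundaries
by how many domains use them, then quantifies how gene content,
transcription-factor binding-site clustering, chromatin accessibility, DNA
double-strand breaks (DSBs) and cross-cell-line conservation change across
the strata. It is aimed at regulatory-genomics analysts who already have TAD
calls (OnTAD-style interval tables), DSB peak BEDs, accessibility bedGraphs,
FIMO motif hits and a gene table, and want the stratified enrichment
analysis — plus a synthetic-data generator with planted ground truth so the
whole pipeline is testable without any download.

## The statistics at the core

**Boundary level.** On the TAD-calling bin grid (10 kb by default), each
distinct TAD endpoint is a boundary bin. With `L` TADs ending and `R` TADs
starting at a boundary, its level is

```
level = min(4, max(L, R))
```

so a boundary used once per side is level 1 and sharing counts of 4+ are
capped at level 4. Level 0 is reserved for non-boundary bins and random
control bins.

**TFCRs.** Transcription-factor binding-site clustered regions are peaks of
an *unnormalized* Gaussian kernel density over TFBS midpoints (bandwidth
300 bp): a hit at distance `d` contributes `exp(-d²/(2·300²)) ∈ (0,1]`, and
hits contributing ≥ 0.1 (within ~644 bp) are a peak's contributors. TFCR
*complexity* is the family-collapsed sum of contributions (max per TF
family, summed over families); each TFCR set is cut into equal-count deciles
TC0–TC9.

**Enrichment.** Associations (e.g. DSB peaks at level-4 boundaries versus a
seeded random sample of non-boundary bins) are tested with an exact 2×2
test: two-sided p by hypergeometric point-probability enumeration, effect
size as the sample odds ratio `(a·d)/(b·c)`.

## Worked example

Simulate a dataset with known planted structure, stratify its boundaries and
test DSB enrichment:

```r
library(tadstrata)
library(dplyr)

cfg <- simulation_config(seed = 42, chrom_sizes = c(chr1 = 3e7, chr2 = 2e7),
                         n_top_tads = 100)
ds  <- simulate_dataset(cfg)

b <- extract_boundaries(ds$tads, cfg$resolution)
level_histogram(b)
#> # A tibble: 4 × 2
#>   level     n
#>   <int> <int>
#> 1     1   278
#> 2     2    37
#> 3     3    20
#> 4     4    10

ctrl <- random_level0_control(b, ds$chrom_sizes, seed = 7)
overlap_fraction_by_level(bind_rows(b, ctrl), ds$dsb_peaks)
#> # A tibble: 5 × 4
#>   level     n n_hit fraction
#>   <int> <int> <int>    <dbl>
#> 1     0   345    31   0.0899
#> 2     1   278    26   0.0935
#> 3     2    37     3   0.0811
#> 4     3    20     8   0.4
#> 5     4    10     3   0.3

high <- filter(b, level >= 3)
fit <- enrichment_vs_background(high[c("chrom", "start", "end")],
                                ctrl[c("chrom", "start", "end")],
                                ds$dsb_peaks,
                                label = "level>=3 boundaries vs level-0 control")
tidy(fit)
#> # A tibble: 1 × 7
#>   label                                   a     b     c     d estimate p.value
#>   <chr>                               <int> <int> <int> <int>    <dbl>   <dbl>
#> 1 level>=3 boundaries vs level-0 con…    11    19    31   314     5.86 1.09e-4
```

The histogram counts boundaries per sharing level (most level 1, a handful
heavily shared, as planted). The fraction table shows the planted DSB
excess concentrating at levels 3–4 (40% and 30% of those bins carry a DSB
peak versus ~9% of random level-0 bins). The exact test quantifies it: 11
of 30 high-level boundary bins overlap a DSB peak versus 31 of 345 control
bins, sample odds ratio 5.9, two-sided p = 1.1e-4.

From files instead of memory, `run_full_analysis(run_config(...))`
orchestrates the same steps (boundary extraction, DSB fractions and exact
tests, TFCR calling with TC classes and promoter/genic/intergenic
annotation, gene boundary levels with flagged-gene enrichment, genome-wide
10 kb bin classification, optional A/B compartment fractions) and writes
TSV/BED outputs plus a `summary.json` that is byte-identical across reruns
with the same seed. Plot helpers (`plot_level_histogram()`,
`plot_overlap_fractions()`, `plot_bin_summary()`, `autoplot()` on profile
matrices) return ggplot objects.

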