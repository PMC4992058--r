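# rechipr

Enrichment calling for ChIP-seq and sequential ChIP (reChIP-seq), and
classification of histone-mark co-occupancy (bivalency) from multiple
enrichment call sets.

## The problem

reChIP-seq precipitates chromatin twice with two different antibodies, so
the sequenced fragments carry both antigens on the same nucleosome — the
direct way to detect bivalent chromatin (H3K4me3 + H3K27me3 on one
nucleosome). These libraries have low signal-to-noise, and their natural
control is the primary ChIP, whose own signal is far from uniform.
`rechipr` calls enrichment with a two-component binomial mixture fitted
jointly to treatment and control counts: for region *i* with control
count *r<sub>i</sub>*, treatment count *s<sub>i</sub>* and total
*n<sub>i</sub> = r<sub>i</sub> + s<sub>i</sub>*,

> s<sub>i</sub> ~ p<sub>B</sub> · Bin(n<sub>i</sub>, θ<sub>B</sub>) +
> (1 − p<sub>B</sub>) · Bin(n<sub>i</sub>, θ<sub>E</sub>),

with background component (weight p<sub>B</sub>, treatment-read
proportion θ<sub>B</sub>) and enrichment component (θ<sub>E</sub> ≥
θ<sub>B</sub>), fitted by multi-start EM. Regions are then tested
one-sided against the fitted background, filtered for achievable
significance (T-method, threshold 10⁻⁴), converted to q-values
(Benjamini–Hochberg by default) and called at chosen FDRs; a
regularized, background-centred log enrichment e\* and its normalized
form e (≈1 at full enrichment) are emitted as tracks. Downstream,
per-track calls for H3K4me3, H3K27me3 and the two reciprocal reChIPs
classify every region into eight co-occupancy classes (unmodified, each
mark alone, pseudo / low / two partial / full bivalency), with a fixed
decision tree mapping promoter classes to genes.

The package also provides fragment-midpoint counting of paired-end
alignments (mapping quality ≥ 20, template length 120–240 bp, duplicates
excluded), ±750 bp TSS window construction, expression-variability (CV)
and Fisher set-enrichment statistics, CpG / CpA+TpG observed-expected
sequence odds, and seeded simulators for counts, alignments and
sequences.

## Worked example

```r
library(rechipr)

sim <- simulate_region_counts(20000, p_b = 0.9, theta_b = 0.4,
                              theta_e = 0.7, seed = 1)
res <- enrich(sim$counts, seed = 1)
res
#> Two-component binomial mixture fit
#>   regions (n > 0): 20000
#>   p_B = 0.8963, theta_B = 0.4000, theta_E = 0.7016
#>   log-likelihood -66362.2754 after 7 iterations (converged)
#>   T-method filter (p <= 0.0001): 20000 of 20000 regions retained
#>   called at FDR 0.001: 2054
#>   called at FDR 0.01: 2088
#>   called at FDR 0.1: 2210
```

The fit recovers the generating parameters (p_B = 0.9, θ_B = 0.4,
θ_E = 0.7): about 90% of regions are background with 40% of their reads
in the treatment library, and the ~10% enriched regions draw 70%. At a
1% FDR, 2,088 of the ~2,070 truly enriched regions are called.
`glance()` returns the parameter row, `augment()` the per-region table
(posterior, p, q, e\*, e, calls), `tidy()` the two components, and
`autoplot()` fit/trace/enrichment diagnostics.

Classification of call sets, and the case for reChIP over intersecting
two primary ChIPs:

```r
coenrichment_diagnostics()
#> # A tibble: 1 × 2
#>   false_positive_pct missed_pct
#>                <dbl>      <dbl>
#> 1               13.7       60.3
```

Using the published TSS class sizes, ~14% of promoters the classical
H3K4me3 ∩ H3K27me3 intersection would call bivalent are pseudo bivalent
(marks on different cells/alleles), and ~60% of truly co-occupied
promoters are missed by it.

A thin command-line front end lives at `inst/cli/rechipr`
(subcommands `count`, `enrich`, `classify`, `simulate`, `seqstats`).

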