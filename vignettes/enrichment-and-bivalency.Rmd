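---
title: "Binomial-mixture enrichment calling and co-occupancy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binomial-mixture enrichment calling and co-occupancy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rechipr)
library(dplyr)
```

## The problem

ChIP-seq enriches chromatin fragments carrying one antigen; sequential
ChIP (reChIP-seq) re-precipitates the eluate with a second antibody, so
the recovered fragments carry both antigens on the same nucleosome. The
canonical application is bivalency: the co-occurrence of the activating
mark H3K4me3 and the repressive mark H3K27me3 at the same promoter.
reChIP libraries have a low signal-to-noise ratio, and their natural
control (the primary ChIP) is itself non-uniform, so peak callers built
around a flat chromatin input perform poorly. `rechipr` addresses this
with a count-based mixture model that *learns* the background from the
data being normalized, then classifies regions into co-occupancy classes
from several such enrichment call sets.

## The model

For region $i$, let $r_i$ be the control fragment count, $s_i$ the
treatment ((re)ChIP) count and $n_i = r_i + s_i$. Conditional on $n_i$,
the treatment count follows a two-component binomial mixture

$$ s_i \sim p_B\,\mathrm{Bin}(n_i, \theta_B) +
   (1 - p_B)\,\mathrm{Bin}(n_i, \theta_E), $$

where $\theta_B$ and $\theta_E$ are the proportions of treatment reads
among all reads in the background and enrichment components, and $p_B$
is the background mixture weight. Conditioning on $n_i$ makes the model
robust to regional coverage variation (mappability, copy number): only
the *split* between treatment and control carries signal. The
log-likelihood is maximized by expectation–maximization with the
standard E-step posterior

$$ z_i = \frac{p_B\,\mathrm{Bin}(s_i; n_i, \theta_B)}
  {p_B\,\mathrm{Bin}(s_i; n_i, \theta_B) +
   (1-p_B)\,\mathrm{Bin}(s_i; n_i, \theta_E)} $$

and M-step updates $p_B = \sum_i z_i / N$,
$\theta_B = \sum_i z_i s_i / \sum_i z_i n_i$,
$\theta_E = \sum_i (1-z_i) s_i / \sum_i (1-z_i) n_i$.

```{r fit}
sim <- simulate_region_counts(20000, p_b = 0.9, theta_b = 0.4,
                              theta_e = 0.7, seed = 1)
res <- enrich(sim$counts, seed = 1)
glance(res)
```

### Numerical and design choices

* **Convergence.** Iteration stops when the absolute log-likelihood
  change drops to `epsilon` (default 0.001) or after `max_iter`
  iterations (default 1000, with a recorded warning and the best
  iterate on non-convergence). Likelihoods and posteriors are computed
  on log probability masses via log-sum-exp.
* **Initialization and restarts.** The deterministic start places both
  $\theta$ symmetrically at $\pm 0.1$ around the pooled proportion
  $s_{tot}/(r_{tot}+s_{tot})$ with $p_B = 0.9$, and `n_starts = 10`
  additional jittered starts (seeded) guard against local maxima; the
  best final likelihood wins.
* **Label order and degenerate solutions.** After fitting, components
  are relabelled so $\theta_B \le \theta_E$: background *means* the
  lower-treatment-proportion component. Among multistart solutions we
  prefer the best one whose background holds the majority of the
  mixture ($p_B \ge 0.5$), falling back to the overall maximum only
  when no start yields one. On data without genuine enrichment the
  unconstrained maximum can be a degenerate fit whose "background" is a
  vanishing lower-tail component; testing everything against that
  component would be anti-conservative, and a background carrying a
  fraction of a percent of regions is not a background in any useful
  sense.
* **Regions with $n_i = 0$.** They carry no information: they are
  excluded from the EM sums, given $z_i = p_B$, $p$-value 1, fail the
  filter, and score $e^*_i = 0$, which keeps all output vectors aligned
  with the input.

## Significance, filtering and q-values

Each region is tested one-sided against the fitted background:
$p_i = P(S \ge s_i \mid n_i, \hat\theta_B)$. Because the test is
discrete, regions with small $n_i$ can never reach significance; the
T-method filter removes tests whose *minimal achievable* $p$-value,
$\hat\theta_B^{\,n_i}$, exceeds 0.0001 before multiple-testing
correction, which restores power for the remaining tests. Retained
$p$-values are transformed to q-values by the monotone step-up rule
with $\pi_0 = 1$ — i.e. Benjamini–Hochberg — by default; a fixed-
$\lambda$ ($0.5$) $\pi_0$ estimate is available behind
`estimate_pi0 = TRUE`. We default to $\pi_0 = 1$ because it is
conservative and exactly reproducible. Calls are thresholded at
q-values of 0.001, 0.01 and 0.1 by default.

## Regularized and normalized enrichment

Raw log ratios explode at low counts. Pseudo counts equal to the
posterior-weighted mean background counts
$\tilde r = \sum z_i r_i / \sum z_i$,
$\tilde s = \sum z_i s_i / \sum z_i$ stabilize the ratio, and
subtracting the background log ratio centres it:

$$ e^*_i = \log_2\frac{s_i + \tilde s}{r_i + \tilde r} -
   \log_2\frac{\tilde s}{\tilde r}. $$

Dividing by the log of the average enrichment factor — the odds ratio
between the two components,
$\log_2\!\big[\tfrac{\theta_E/(1-\theta_E)}{\theta_B/(1-\theta_B)}\big]$
— yields the normalized enrichment $e_i$, which is $0$ for a typical
background region and $\approx 1$ for a region enriched exactly as the
enrichment component predicts. The divisor is undefined when
$\hat\theta_B = \hat\theta_E$ (no enrichment component); $e^*$ is still
returned.

```{r scores, fig.width = 5, fig.height = 3.5}
ggplot2::autoplot(res, type = "fit")
```

## Fragment counting

Counts are made from paired-end alignments by fragment midpoints: each
properly paired fragment is represented once (its leftmost mate), kept
if mapping quality $\ge 20$, absolute template length within the
*closed* interval $[120, 240]$ (mono-nucleosome-sized), and no
duplicate flag (bit 1024); its counting position is
$\mathrm{pos} + \lfloor |\mathrm{tlen}|/2 \rfloor$. Regions follow the
BED convention (0-based, half-open), so the default TSS windows of
$\pm 750$ bp around a transcription start site are exactly 1500 bp;
pipelines using inclusive windows (1501 bp) differ by one base at the
right edge. Transcripts sharing TSS, strand and gene name are merged,
represented by the transcript with the most RNA-seq reads in its first
exon (ties broken lexicographically by transcript id — the convention
is arbitrary but deterministic). On the template-length bounds we
follow the inclusive interval of the counting configuration rather
than the stricter reading "longer than 120 and shorter than 240";
fragments of exactly 120 or 240 bp are kept.

## Co-occupancy classification

Given over-input calls for the two primary ChIPs ($A$, $B$) and the
two reciprocal reChIPs ($reBA$, $reAB$), each region maps to one of
eight classes: `unmodified`, `A_only`, `B_only`, `pseudo` (both
primaries, no reChIP — the marks live on different cells or alleles),
`low_cooccupancy` (reChIPs only), `A_partial` / `B_partial` (one
primary plus both reChIPs — heterogeneous co-occupancy), and
`full_bivalent` (all four). Co-occupancy always requires *both*
reciprocal reChIPs, so the eight patterns cover the half of the
$2^4$ truth table where the reChIP calls agree; the other eight
combinations (a lone reChIP call) are resolved by discounting the lone
call and re-classifying, with an `irregular` flag so downstream
analyses can inspect or drop them. A six-ratio mode additionally uses
the reChIP-over-primary calls to define the three bivalent classes
more stringently, falling back to the four-call rule elsewhere.
Promoter classes map to genes through a fixed precedence
(`A_only` > `A_partial` > `pseudo` > `full_bivalent` > `B_partial` >
`B_only` > `unmodified`); `low_cooccupancy` promoters are ignored by
the tree. Regions with a zero count in the control or any (re)ChIP
track should be removed beforehand (`drop_unobserved_regions()`).

Why reChIP at all? With the published class sizes over ~72,000 human
TSSs, intersecting the two primary ChIP call sets — the classical
definition of bivalency — both overcalls and undercalls co-occupancy:

```{r diag}
coenrichment_diagnostics()
```

About 14% of intersection-bivalent promoters are pseudo bivalent, and
about 60% of truly co-occupied promoters (the partial classes) are
invisible to the intersection.

## Sequence statistics

`sequence_stats()` reports G+C%, CpG%, and observed/expected odds for
CpG and CpA/TpG with expectations formed from the sequence's own base
frequencies: $\#CG / [(L-1)(n_C/L)(n_G/L)]$ and the analogous
two-term expectation for CpA+TpG. CpA/TpG excess indicates historical
deamination of methylated CpGs, i.e. germline methylation. Ambiguous
bases are excluded from base counts, the effective length, and
dinucleotide windows on both the observed and expected side. For
i.i.d. bases the CpG odds converge to 1, which the simulator
reproduces.

## What the simulators emulate — and what they do not

`simulate_region_counts()` draws directly from the generative mixture:
a latent component per region, totals from a truncated Poisson (mean
100 by default — the conditional structure of the model does not
constrain how totals arise, so a simple overdispersion-free choice is
used), and a binomial treatment split. It therefore tests parameter
recovery, calibration and FDR control *under the model*. Real ChIP
data violate the model in known ways — overdispersion beyond binomial,
spatial autocorrelation between neighbouring windows, copy-number and
mappability artifacts — so passing tests demonstrate correctness of
the machinery, not robustness to every artifact of real libraries.
`simulate_alignments()` builds deterministic proper-pair SAM fixtures
with controlled template lengths, qualities and flags (read sequences
are homopolymers; base qualities are constant — realistic sequence
content is out of scope). `simulate_call_tracks()` composes the four
call tracks from a latent 8-class label with a per-track detection
probability; it makes no claim of matching any particular biology.

## Problem sizes and reproducibility

The bundled checks use 20 recovery replicates and 50 null plus 50
mixed replicates at 20,000 regions (5,000 for the pure-null case, where
the quantity of interest — a mean call rate — stabilizes quickly), and
25 instances of at most 50 regions for the exhaustive grid-search
comparison at grid step 0.01; these sizes give Monte-Carlo error
comfortably below the tolerances being checked while keeping a full
run in the minutes range. All randomness flows through explicit seeds;
`scripts/acceptance.R` derives every task seed from a single `--seed`.

## Known limitations

* Two components only; multi-regime enrichment (e.g. broad domains at
  several intensity levels) needs a different model.
* Differential enrichment between two ChIPs is out of scope; the
  control is always the appropriate background library.
* The binomial split ignores overdispersion between replicate
  libraries; q-values are calibrated under the fitted model.
* CpG islands are consumed as user-supplied regions; no island
  prediction from sequence is performed.
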