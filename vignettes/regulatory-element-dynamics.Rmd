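---
title: "Methods: quantifying enhancer and promoter dynamics across DNA-damage timepoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enhancer and promoter dynamics across DNA-damage timepoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`credyn` analyses the temporal behaviour of cis-regulatory elements —
enhancers and promoters — across three ordered treatment timepoints (by
default 0 h, 8 h and 16 h of genotoxic stress, representing pre-damage,
moderate and severe DNA damage). It starts from *processed* inputs: element
catalogs (BED), gene models, per-timepoint fragment sets with library sizes,
peak calls, TF footprint tables, chromatin loops, and differential-expression
tables. Read alignment, peak calling, footprint calling and DE model fitting
are upstream of this package by design.

The analysis proceeds in stages:

1. **Curation.** Candidate enhancers overlapping coding regions (the full
   gene span extended by 1 kb on both sides) or blacklist intervals are
   removed; survivors are classified *proximal* (1–2 kb upstream of the
   nearest TSS) or *distal* (> 2 kb upstream). Promoters take the strand of
   their nearest TSS.
2. **Quantification.** Element signal is reads per million (RPM): fragments
   overlapping the element by ≥ 1 bp divided by the library's total mapped
   fragments, × 10⁶. An element is *expressed* when its 0 h RPM is > 0.
3. **States and trajectories.** At each timepoint an element is accessible
   (ATAC) or active (H3K27ac) iff it shares ≥ 1 bp with a peak, and
   expressed (RNA) iff its RPM > 0. A three-timepoint trajectory is
   *consistent_positive* when all three states are positive,
   *consistent_negative* when all are negative, and *dynamic* otherwise.
   Random 2-kb regions (length-weighted uniform placement) and random
   accessible regions (peaks sampled without replacement after excluding
   catalog elements) serve as controls.
4. **Target genes and coordinated pairs.** Enhancers are linked to genes by
   (a) basal-plus-extension regulatory domains — a 5 kb upstream / 1 kb
   downstream basal region around each TSS, extended up to 1 Mb but never
   past a non-overlapping neighbour's basal region or a chromosome edge —
   and (b) chromatin loops with one anchor on the enhancer and the other on
   the gene's promoter. A pair is *coordinated* when enhancer RPM and gene
   expression both change strictly in the same direction at both steps.
5. **TF activity and p53.** Per-TF binding activity at each timepoint is the
   mean footprint score; TFs are ranked by the sample standard deviation of
   the activity triple, descending, and elements are partitioned into
   p53-bound and p53-free classes by p53 peak overlap.
6. **Statistics.** Paired comparisons across the three timepoints use the
   Friedman rank test with tie correction; distribution comparisons between
   element groups use the unpaired two-sample Kolmogorov–Smirnov test. Stars
   follow strict thresholds (\*, \*\*, \*\*\*, \*\*\*\* at p < 0.05, 0.01,
   0.001, 0.0001).

# Statistical details

**Friedman.** Within-row mid-ranks; the tie-corrected statistic is
$Q = \left[\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)\right]/C$ with
$C = 1 - \sum(t^3-t)/(nk(k^2-1))$ over within-row tie groups. For $n \le 6$
the p-value is exact, by enumerating all $(k!)^n$ within-row permutations of
the observed values (ties preserved); larger $n$ uses the $\chi^2_{k-1}$
upper tail, and the method used is recorded in the result. Fully tied data
yield $Q = 0$, $p = 1$ by convention. A useful closed form for sanity
checks: $n$ strictly increasing rows at $k = 3$ give exactly $Q = 2n$.

**Kolmogorov–Smirnov.** $D = \sup_t |\hat F_x(t) - \hat F_y(t)|$ over the
pooled observed points. When $m + n \le 20$ and the samples share no value,
the p-value is exact — a lattice-path count over all $\binom{m+n}{n}$
orderings of paths whose running CDF difference stays strictly below the
observed $D$. Otherwise the two-sided asymptotic series
$p = 2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2e^2}$ is used with the small-sample
effective-size correction
$e = (\sqrt{mn/(m+n)} + 0.12 + 0.11/\sqrt{mn/(m+n)})\,D$, truncated when
terms fall below 1e-10 and clamped to [0, 1]. Cross-sample ties force the
asymptotic path (noted in the result), since the exact distribution is
ill-defined without a tie-breaking convention.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pad` | 1000 | bp | coding-region extension on both sides of each gene span |
| proximal band | (1000, 2000] | bp | upstream distance from nearest TSS to enhancer midpoint |
| `basal_up`/`basal_down` | 5000 / 1000 | bp | regulatory-domain basal region around the TSS |
| `max_ext` | 1e6 | bp | maximum domain extension per side |
| `lfc_min`, `fdr_max` | 1, 0.05 | — | strict DE-consistency thresholds in both contrasts |
| `eps` | 0 | signal units | minimum step change for coordination (0 = strict monotonicity) |
| `top_n` | 30 | TFs | highly variable TF list length |
| `flank`, `bin`, `smooth` | 1000, 50, 60 | bp | profile-matrix window, bin width and smoothing window |

Design choices where the convention was genuinely open:

- **Distance reference point** is the enhancer midpoint
  (`floor((start+end)/2)`), symmetric and consistent with center-anchored
  profile plotting. Enhancers downstream of every gene fall back to the
  unsigned distance to the nearest TSS.
- **RPM counts fragments** overlapping by ≥ 1 bp rather than averaging
  per-base coverage: the simplest contract consistent with
  "reads per million".
- **Promoter strand** is assigned by nearest TSS with a lexicographic
  gene-id tie-break, which is deterministic and dependency-free.
- **TF activity metric**: footprint callers emit both a protection score and
  a tag count without a canonical fusion; the default `combined` metric is
  the mean of the two after table-wide min–max normalisation, and
  `protection` or `tag_count` alone are available. Ranking uses the sample
  SD (divisor n − 1) with lexicographic tie-breaks.
- **DE consistency** is realized as passing the thresholds with the same
  sign in both the 8h-vs-0h and 16h-vs-0h contrasts.
- **Coordinated-pair evidence**: pairs carry their provenance (`domain`,
  `loop`, `both`) and the caller filters. Recovery metrics against the
  synthetic truth score loop-anchored pairs only, because class-wide
  temporal profiles (e.g. monotone-decreasing proximal RNA) can make
  domain-only pairs genuinely co-vary without being individually planted.
- **Smoothing** averages all bins overlapping the `smooth`-bp window centred
  on each bin, truncated at matrix edges (no padding); with the 50/60
  defaults this is a three-bin moving mean. Minus-strand rows are reversed
  so bins run 5′→3′.

# The synthetic-data generator

`synth_config()` / `generate_bundle()` emit a complete bundle whose defaults
*are* the study conditions the package is tested under: ~2,000 elements
(900 distal enhancers, 300 proximal enhancers, 800 promoters over 800 gene
slots on two chromosomes), negative-binomial fragment counts
(`baseline_rate` 20 per element at 0 h, `dispersion` 0.3), 15% silent
elements, 40 planted coordinated pairs plus 40 loop-connected distractors,
40 TFs of which 5 have high cross-timepoint activity variance (variance
separation far above 5×), 30% p53-bound elements, and 5% peak-boundary
jitter. Class-level multiplicative temporal profiles encode the
damage-response shapes: distal-enhancer signal drops at 8 h and rebounds
above baseline at 16 h — RNA (1.0, 0.6, 1.2), ATAC (1.0, 0.7, 1.1),
H3K27ac (1.0, 0.6, 1.2) — while proximal-enhancer and promoter RNA decline
monotonically (1.0, 0.7, 0.5).

Counts are negative-binomial rather than Poisson so group comparisons face
realistic overdispersion. Peaks derive from planted states with boundary
jitter as the only state noise, keeping state-recovery tests free of
peak-caller confounding. Every library's `total_count` is a fixed library
size (10⁶) exceeding the emitted fragments, reflecting real libraries in
which reads outside the element catalog dominate the per-million
denominator; without this, per-million normalisation would cancel the very
temporal profiles the bundle plants. Planted-pair expression triples are
deterministic monotone shapes (down: 2.2→1.3→0.6 relative) under lognormal
noise (`pair_noise_sd` 0.1); setting `dispersion`, `jitter_frac` and
`pair_noise_sd` to 0 gives the noise-free bundle in which every planted fact
is recovered exactly.

What the generator does *not* emulate: mappability and GC bias, overlapping
or nested elements, peak-caller false positives/negatives, spatial
correlation of fragments, biological replicates, and genome-scale intergenic
background reads. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under controlled conditions, not its
robustness to every artefact of real sequencing data.

Problem sizes used in the test-suite checks are the generator defaults
(~2,000 elements; 20 seeds for the trend-direction check; 10,000 simulated
null datasets at n = 20 for the Friedman calibration), chosen as the
smallest sizes at which the planted effects and the Monte-Carlo bands are
informative.

# Degenerate inputs and numerical conventions

- Intervals are 0-based half-open on disk (BED) and validated on read;
  overlap always means ≥ 1 shared base, so abutting intervals do not
  overlap.
- Profile windows extending past a chromosome edge are truncated and the
  missing bases count as zero coverage.
- An empty gene list removes nothing during coding-overlap filtering;
  distance classification requires at least one gene on the element's
  chromosome.
- TFs missing a timepoint are dropped from activity tables with a logged
  reason; pairs missing expression for either member are dropped likewise.
- Exhausting the eligible pool of random accessible regions returns all
  eligible peaks with a `truncated` flag and a warning.
- All seeded operations restore the caller's RNG state, so results are pure
  functions of (inputs, seed); pipeline manifests record relative paths so
  identical runs are byte-identical wherever they execute.

# Known limitations

- Coding regions are approximated by the full gene span (TSS to TES) ± 1 kb;
  no exon-level resolution.
- The trajectory machinery assumes exactly three ordered timepoints; the
  Friedman test itself accepts any k ≥ 2, but closed-form checks and the
  trajectory vocabulary are specific to k = 3.
- Loop anchors are matched by simple overlap; no loop strength or FDR is
  modelled.
- No multiple-testing correction is applied across comparison panels; stars
  are per-test, matching the reporting convention the pipeline follows.
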