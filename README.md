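# credyn — dynamics of cis-regulatory elements under DNA damage

`credyn` is an R package for analysing how enhancers and promoters change
across three ordered treatment timepoints (0 h, 8 h, 16 h of genotoxic
stress: pre-damage, moderate and severe DNA damage). It is aimed at
regulatory-genomics analysts who already have processed multi-omics inputs —
element catalogs (BED), gene models, per-timepoint RNA/ATAC/H3K27ac fragment
sets, peak calls, TF footprint tables, chromatin loops and
differential-expression tables — and want a tested, deterministic pipeline
from those inputs to state trajectories, coordinated enhancer–gene pairs,
TF-activity rankings and p53 partitions.

## What it computes

- **Element curation** — candidate enhancers overlapping coding regions
  (gene span ± 1 kb) or blacklist intervals are removed; survivors are
  *proximal* (1–2 kb upstream of the nearest TSS, measured at the enhancer
  midpoint) or *distal* (> 2 kb upstream).
- **Signal** — per-element reads per million,
  `RPM = overlapping fragments / total mapped fragments × 10⁶`; an element
  is *expressed* when RPM > 0 at 0 h. Center-anchored, binned (50 bp),
  CPM-normalised, smoothed (60 bp) profile matrices are also available.
- **State trajectories** — at each timepoint an element is
  accessible/active iff it overlaps a peak by ≥ 1 bp (expressed iff
  RPM > 0); the triple is *consistent_positive* (all three),
  *consistent_negative* (none) or *dynamic*. Random-region and
  random-accessible-region controls are drawn with seeded samplers.
- **Enhancer→gene pairs** — basal-plus-extension regulatory domains
  (5 kb/1 kb basal, ≤ 1 Mb extension) and chromatin-loop anchors; a pair is
  *coordinated* when enhancer RPM and gene expression change strictly in
  the same direction at both steps.
- **TF footprint variability** — per-TF binding activity (mean protection
  score / tag count / min–max-combined) per timepoint; TFs ranked by the
  sample standard deviation of the activity triple, top 30 by default;
  p53-bound vs p53-free element partitions.
- **Statistics** — paired Friedman rank test with tie correction,

  `Q = [(12 / (n·k·(k+1))) · Σⱼ Rⱼ² − 3·n·(k+1)] / C`,

  exact for n ≤ 6 by enumerating all (k!)ⁿ within-row permutations, else
  χ²(k−1); and the unpaired two-sample Kolmogorov–Smirnov test,
  `D = sup |F̂ₓ − F̂ᵧ|`, exact for pooled sizes ≤ 20 without cross-sample
  ties, else the asymptotic series with small-sample correction.
  Stars: \*, \*\*, \*\*\*, \*\*\*\* at p < 0.05, 0.01, 0.001, 0.0001.

A seeded synthetic-data generator (`generate_bundle()`) emits a complete
input bundle with planted classes, state trajectories, coordinated pairs,
high-variance TFs and p53-bound elements, so the entire pipeline is testable
without any external download.

## Worked example

Run the full pipeline on the default synthetic study conditions
(~2,000 elements) and inspect what it recovered:

```r
library(credyn)
cfg <- run_config(seed = 1, out_dir = file.path(tempdir(), "demo"))
run_pipeline(cfg)

read.table(file.path(cfg$out_dir, "report", "recovery.tsv"), header = TRUE)
#>        stage             metric value
#> 1 trajectory      ATAC_recovery     1
#> 2 trajectory   H3K27ac_recovery     1
#> 3 trajectory       RNA_recovery     1
#> 4      pairs          precision     1
#> 5      pairs             recall     1
#> 6      tfdyn      top_tf_recall     1
#> 7        p53 partition_accuracy     1
```

Every planted trajectory category, coordinated pair (loop-anchored),
high-variance TF and p53 label was recovered. The per-group trend tests show
the planted damage-response shapes — distal-enhancer RNA drops at 8 h and
rebounds above baseline at 16 h, while proximal-enhancer and promoter RNA
decline monotonically — all Friedman-significant:

```r
tr <- read.table(file.path(cfg$out_dir, "compare", "trend_tests.tsv"), header = TRUE)
tr[tr$assay == "RNA", c("group", "n", "mean_0h", "mean_8h", "mean_16h", "p_value", "stars")]
#>     group   n  mean_0h  mean_8h mean_16h      p_value stars
#>    distal 900 17.47778 11.14889 22.02333 2.936513e-62  ****
#>  proximal 300 18.10333 12.84000  8.49000 5.007969e-26  ****
#>  promoter 800 16.76250 11.48875  8.16250 1.255709e-63  ****
```

(Means are per-element RPM at 0 h / 8 h / 16 h; the p-values are
tie-corrected Friedman chi-square tests across the three paired timepoints.)

The statistical primitives are usable on their own:

```r
friedman(matrix(c(3, 2, 1,  5, 4, 2,  9, 7, 8), nrow = 3, byrow = TRUE))
#> friedman_exact: statistic = 4.66667, p = 0.1944 ns
ks2(c(1.2, 3.4, 2.2, 5.0), c(6.1, 7.3, 8.8, 9.9))
#> ks_exact: statistic = 1, p = 0.02857 *
```

Stage by stage, the same run is available as
`run_stage("simulate", cfg)`, `run_stage("curate", cfg)`, …, each writing
TSV outputs and a `manifest.json` under `<out_dir>/<stage>/`, or from a
shell via `Rscript inst/scripts/credyn.R <stage> --config run.yaml`.
Reruns with the same configuration are byte-identical.

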