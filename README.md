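# nfkbtrace

Single-cell quantification of NF-κB nuclear translocation dynamics and
TNFα-promoter reporter activation from multi-channel time-lapse microscopy.

## The problem

Macrophages expressing EGFP-tagged p65 and a TNFα-promoter-driven mCherry
reporter are imaged by confocal time-lapse (EGFP, mCherry, bright-field;
512 × 512 px; one frame every 3 min for up to 15 h) after LPS stimulation.
NF-κB activation is visible as transient redistributions of EGFP from the
cytoplasm into the nucleus; promoter activity accumulates as mCherry. The
analysis task is to turn those movies into per-cell dynamics and group
statistics:

* **Nuc/Cyt ratio** per frame: mean nuclear EGFP ÷ mean cytosolic EGFP
  (cell body minus a nuclear circle), smoothed by a centred ten-frame
  average — the translocation curve
  `r(t)`;
* **Cell/BG ratio** per frame: mean cellular mCherry ÷ mean background —
  the reporter curve;
* **peaks** of `r(t)` above a noise level estimated from unstimulated
  cells, each with initiation time (last upward crossing of the detection
  level before the maximum), peak time, height, and nuclear duration
  (peak − initiation time);
* the per-cell panel: peak count, inter-peak intervals (~90 min in wild
  type), damping rates `(h_k − h_{k+1}) / h_k`, and the mCherry fold
  increase (max ÷ baseline mean, 1 = no induction);
* **Kruskal–Wallis** omnibus tests with **Dunn's** multiple-comparison post
  hoc across genotypes (WT, TRIF⁻/⁻ "TKO", MyD88⁻/⁻ "MKO", double-KO
  "DKO").

Cells that touch another cell, divide, clip the image border, or cannot be
tracked for the whole movie are excluded — the single-cell measurements are
only meaningful for isolated, complete tracks.

Because no raw movies are publicly available for this design, the package
also contains a **synthetic-movie generator**: damped Gaussian pulse trains
for the nuclear fraction, logistic-rise reporter profiles, per-genotype
presets, and a renderer with PSF blur, Poisson shot noise and read noise.
Every pipeline stage is validated by parameter recovery against that
forward model's ground truth.

## Worked example

Simulate a wild-type and a double-knockout cohort, run the full pipeline
(segment → track → exclude → extract → score → compare), and inspect the
result:

```r
library(nfkbtrace)

cfg <- run_config(
  simulate = list(genotypes = c("WT", "DKO"), n_per_group = 6,
                  n_unstimulated = 6,
                  optics = optics_params(image_size = 200, n_frames = 150)),
  seed = 7, out_dir = "results/demo")
res <- run_experiment(cfg)
#> [noise] threshold 0.0349 from 6 unstimulated cells

aggregate(cbind(n_peaks, fold) ~ genotype, res$metrics, median)
#>   genotype n_peaks    fold
#> 1      DKO       0 1.01204
#> 2       WT       3 2.27091

res$comparisons$n_peaks
#> Kruskal-Wallis: H = 9.116, df = 1, p = 0.002534 (n = 11)
#> Dunn pairwise (bonferroni-adjusted):
#>  group1 group2        z     p_unadj       p_adj stars significant
#>      WT    DKO 3.019275 0.002533803 0.002533803    **        TRUE
```

The unstimulated cohort sets the peak-calling threshold (here 0.035 ratio
units above each cell's median). Wild-type cells then show a median of 3
translocation peaks and a ~2.3-fold reporter increase; the double knockout
shows no peaks and no induction, and the peak-count difference is
significant after Dunn adjustment. `results/demo/` contains the trace,
metric, summary, comparison and exclusion CSVs plus a `manifest.json`
whose MD5 stamps every CSV.

The `analysis/` directory decomposes the same workflow into numbered
stages over five simulated cohorts (`01_simulate.R` → `04_stats.R`),
writing movies under `scratch/movies/` and tables under `results/`.

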