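# sstbench

Benchmarking toolkit for **sequencing-based spatial transcriptomics
(sST)** — spot arrays, bead lawns and related platforms that capture
tissue mRNA on spatially barcoded substrates and read it out by
sequencing.

Platform comparisons in this field hinge on a small set of recurring
computations that are easy to get subtly wrong: sensitivity must be
compared at *matched* sequencing depth; lateral diffusion of transcripts
must be quantified from 1-D intensity profiles; clustering robustness
under downsampling needs proper agreement metrics. `sstbench` implements
these statistics as tested, reusable functions for method developers and
core facilities evaluating sST platforms:

* **Depth & saturation** — exact without-replacement read downsampling
  over molecule tables (per-molecule retained reads are multivariate
  hypergeometric), depth matching across platforms, UMI saturation
  curves, and the closed-form expectation
  `E[UMIs] = Σ_m [1 − C(R−r_m, T)/C(R, T)]` used as its own oracle.
* **Sensitivity** — total-UMI sums in regions of interest and
  marker-gene sums in fixed windows (50 × 50 µm default), with platform
  ranking at common depth.
* **Lateral diffusion** — strip intensity profiles across histological
  boundaries, peak alignment and averaging, unit-area normalization,
  and the **left width at half maximum (LWHM)**: the distance from the
  profile peak leftward to the interpolated half-maximum crossing.
  A DBSCAN-based dispersion surrogate covers sparsely expressed genes.
* **Clustering agreement** — contingency tables and the entropy of
  cluster accuracy / purity:
  `ECA = −(1/M) Σ_i Σ_k p_ik ln p_ik` with `p_ik = n_ik / n_i·`
  (and ECP as its mirror over reference classes); 0 = perfect agreement.
* **Marker detection** — Wilcoxon rank-sum marker tables
  (exact small-sample p values), the three-threshold marker filter
  (detection > 5%, log FC > 0.25, BH-adjusted P < 0.01), marker counts
  versus depth, and cross-platform intersection partitions.
* **Capture bias & contamination** — pairwise percentile rules
  (99th/10th and 90th/10th presets), multi-platform bias-gene flagging,
  ANOVA on GC content and gene length, biotype summaries, and the
  ambient-contamination spot-positivity fraction.
* **Synthetic data** — a seeded generator (ring or layered tissue
  layouts, region expression programs, Gaussian lateral diffusion,
  shifted-Poisson read duplication, ambient contamination) with full
  ground truth, so every statistic is validated by parameter recovery.

See the vignette `vignettes/benchmarking-methods.Rmd` for the models,
conventions and design decisions.

## Worked example

The demo scenario simulates two platforms on an embryonic-eye-like ring
layout (lens / neural retina / melanocyte ring): platform `alpha` with
tight diffusion (σ = 2 µm) and low ambient contamination, platform
`beta` with strong diffusion (σ = 12 µm), smaller capture spots and
heavier contamination.

```r
library(sstbench)
cfg <- demo_config(file.path(tempdir(), "demo"), seed = 1)
summary <- run_full_benchmark(cfg)

read.csv(file.path(cfg$out_dir, "sensitivity.csv"))
#>   platform total_umi window_mean window_sd n_windows rank
#> 1    alpha      4832       450.4 116.27682         5    1
#> 2     beta      2642       210.6  40.01625         5    2

read.csv(file.path(cfg$out_dir, "lwhm_summary.csv"))
#>   platform n_defined median_lwhm  iqr_lwhm rank
#> 1    alpha         3    7.826087 3.8679245    1
#> 2     beta         3   13.888889 0.9615385    2

unlist(summary$contamination_fraction)
#>      alpha       beta
#> 0.08888889 0.10222222
```

Reading the output: at common read depth, `alpha` recovers more UMIs in
the lens ROI (4,832 vs 2,642) and in the five 50 × 50 µm marker windows
(mean 450 vs 211), so it ranks first on sensitivity. Its median LWHM at
the melanocyte ring boundary is smaller (7.8 vs 13.9 µm), reflecting the
tighter generative diffusion; and a smaller fraction of its spots
contain the blood-like ambient gene. The run also writes saturation
curves, ECA/ECP concordance under downsampling, per-platform marker
tables and capture-bias flags to `cfg$out_dir` (see `summary.json` for
the machine-readable digest).

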