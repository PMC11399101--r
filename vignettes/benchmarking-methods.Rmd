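---
title: "Benchmarking sequencing-based spatial transcriptomics: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking sequencing-based spatial transcriptomics: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstbench)
```

# The problem

Sequencing-based spatial transcriptomics (sST) platforms capture mRNA on
spatially barcoded substrates — spot arrays, bead lawns, DNA nanoball
chips — and read the result out by sequencing. Platforms differ in spot
pitch (center-to-center distance), capture chemistry and depth, so three
quality axes dominate any comparison:

* **capture sensitivity** — how many distinct molecules (UMIs) are
  recovered per unit tissue area, at a *matched* sequencing depth;
* **spatial accuracy** — how far transcripts diffuse laterally from
  their tissue origin before capture, blurring histological boundaries;
* **downstream robustness** — whether clustering and marker detection
  survive reduced sequencing depth.

`sstbench` implements the statistics for all three axes, plus the
supporting machinery (I/O, QC, normalization, ROI selection) and a
synthetic data generator with known ground truth so that every statistic
can be validated end to end.

# Data model

A dataset is a sparse spots-by-genes matrix of UMI counts with spot
center coordinates in micrometres (`spatial_counts`). Where read-level
information matters — depth matching, saturation — the substrate is the
`molecule_table`: one row per captured molecule carrying its read
multiplicity. Collapsing molecules per spot and gene reproduces the
count matrix exactly; this invariant is tested.

Conventions used throughout, chosen to avoid double counting and made
deterministic on the boundary:

* grid cells, windows and strip bins are half-open `[a, b)`;
* membership is always by spot *center*;
* a center exactly on an ROI polygon edge counts as inside;
* Matrix Market files are 1-based on disk, as the format prescribes.

# Quality control and normalization

Spots whose total counts fall below 30% of the first quartile of
per-spot totals are removed (`filter_low_quality`). "First quartile"
means the 25th percentile with type-7 linear interpolation — R's default
and the only reading under which the 30% multiplier gives a meaningful
threshold; a 1st-percentile reading would filter almost nothing.
Normalization (`normalize_median`) rescales each spot to the median of
per-spot totals, the per-platform scaling factor: normalized rows all
sum to the median total.

# Depth matching and saturation

Cross-platform sensitivity comparisons are confounded by sequencing
depth, so reads are downsampled to a common total first.
`downsample_reads` draws exactly the target number of reads uniformly
*without replacement* from the pooled reads — the same operation as
selecting read IDs from an alignment — so per-molecule retained counts
are multivariate hypergeometric. A molecule survives iff at least one
read is retained. The closed form

$$\mathbb{E}[\mathrm{UMIs}] \;=\; \sum_m \left[1 -
\binom{R-r_m}{T}\Big/\binom{R}{T}\right]$$

(`expected_umis`; $R$ total reads, $r_m$ reads of molecule $m$, $T$ the
target) is the independent oracle the stochastic path is tested against:
Monte-Carlo means agree within three standard errors, and the curve is
nondecreasing and discretely concave in $T$. Binomial thinning (each
read kept independently) is available behind `mode = "binomial"` for
users who want the simpler model; it does not return an exact read
total. Proportions convert to read counts by round-half-up, documented
so runs are reproducible. The default saturation proportions (0.1–1 in
steps of 0.1) are a package choice; published axes vary by study and are
configurable.

# Sensitivity statistics

`roi_total_umi` sums counts over an ROI-selected dataset;
`window_marker_sum` sums marker-gene counts in fixed rectangles,
reporting per-window values, mean and s.d. The 50 × 50 µm default window
follows the convention of sizing windows by the coarsest platform
resolution in the comparison. `compare_platforms_sensitivity` ranks
platforms by mean window sum, with a documented tie-break (ROI total,
then name) since real comparisons rarely tie but synthetic ones can.
When depth matching is requested, molecule tables are first restricted
to the selected spots, then downsampled to the common minimum — reads
are matched *within* the compared region, not genome-wide.

# Lateral diffusion: strip profiles and LWHM

A *modality* is a rectangular strip (default 50 µm wide, 10 µm bins)
laid across a histological boundary where a marker gene should fall off
sharply. Spot centers within half the strip width of the axis are
projected onto it and binned; the profile peak is the leftmost argmax
bin. Profiles from several modalities can be aligned on their peaks and
averaged over the overlapping support (`align_and_average`), after
dropping modalities with fewer than `min_total` counts. The filter
cutoff defaults to 10 counts; the filter itself is standard practice but
no published cutoff exists, so it is a configurable package default.
`normalize_auc` rescales a profile to unit area for cross-platform
density plots.

The diffusion statistic is the **left width at half maximum**
(`lwhm`): from the peak, scan left to the first bin strictly below half
the peak value and linearly interpolate the crossing between that bin
and its right neighbor; LWHM is the peak-to-crossing distance. Only the
left side is used because genuine expression of the marker may continue
on the right side of the chosen boundary; the left flank isolates
diffusion. Profiles that never drop below half to the left (flat,
monotone-left, or peaked at the first bin) have no LWHM and are
excluded rather than erroring — mirroring how undefined modalities are
removed from boxplots. LWHM is invariant to positive scaling, hence
identical on raw and AUC-normalized profiles; tests assert both, plus
the closed forms: the symmetric 9-bin triangle gives exactly 20 µm, and
a finely binned Gaussian of s.d. $\sigma$ gives
$\sigma\sqrt{2\ln 2} \approx 1.177\,\sigma$.

For sparsely expressed genes (the *Sst*-like case) the package offers a
dispersion surrogate: DBSCAN on the coordinates of expressing spots,
then per-cluster variance of member distances. "Variance in distances"
is ambiguous in the field; the default is variance of distances to the
cluster centroid, with pairwise-distance variance behind
`variance = "pairwise"` — both are provided rather than guessing a
single intent. DBSCAN defaults (`eps = 2 * pitch`, `min_pts = 3`) are
package choices sized to spot arrays and always logged in the output.
The DBSCAN itself is a compact internal implementation (plain Euclidean,
quadratic neighbor search), adequate for the few hundred expressing
spots this analysis sees.

# Clustering agreement: ECA and ECP

Given a predicted clustering and a reference labeling over a shared
spot universe, the contingency table $n_{ik}$ counts spots in predicted
cluster $i$ and reference class $k$. Two entropy summaries:

$$\mathrm{ECA} = -\frac{1}{M}\sum_{i=1}^{M}\sum_{k} p_{ik}\ln p_{ik},
\qquad p_{ik} = n_{ik}/n_{i\cdot}$$

$$\mathrm{ECP} = -\frac{1}{N}\sum_{k=1}^{N}\sum_{i} q_{ki}\ln q_{ki},
\qquad q_{ki} = n_{ik}/n_{\cdot k}$$

with $0\ln 0 := 0$ and natural logarithms (the published formulas write
`log` without base; the natural-log convention is documented so values
are comparable). ECA is zero iff every predicted cluster is pure; ECP is
zero iff every reference class sits in one predicted cluster; the two
are mirror images, $\mathrm{ECP}(p, r) = \mathrm{ECA}(r, p)$, which the
tests exploit against a brute-force entropy oracle. Spots present in
only one labeling are dropped, with the count reported. The typical use
is `downsample_concordance`: full-data cluster labels as reference, one
(ECA, ECP) pair per downsampling proportion. Clustering algorithms
themselves are out of scope — labels are inputs; a k-means
`demo_cluster_labels` exists only so the demo pipeline can run
self-contained.

# Marker detection

`wilcoxon_markers` compares median-normalized expression between two
spot groups per gene with a two-sided Wilcoxon rank-sum test: exact when
the combined group size is ≤ 25 and the gene has no ties, otherwise the
normal approximation with tie and continuity corrections (both via
`stats::wilcox.test`). The log fold change is
$\ln\!\big((\bar x_1+\varepsilon)/(\bar x_2+\varepsilon)\big)$ with
$\varepsilon = 10^{-9}$ — a deliberate simplification of the
expm1-of-log-means formula some toolkits use, documented because the
thresholds below are calibrated on "log fold change" generically.
P values are BH-adjusted across all tested genes, with no pre-filtering
before adjustment. `filter_markers` applies the three-part marker
definition with *strict* inequalities: detection fraction in the
up-group > 0.05, log FC > 0.25, adjusted P < 0.01. The 5% detection
threshold is applied to the up-regulated group only (the "specific
spots"); applying it to both groups would discard genes cleanly absent
from the other group, which is exactly the signature of a good marker.
`marker_depth_curve` reruns the full chain (downsample → re-quantify →
re-normalize → test → filter) per proportion; `marker_intersection`
partitions per-platform marker sets by membership signature
(all-shared / partially shared / unique).

# Capture bias and contamination

`pairwise_gene_compare` flags genes at or above the `high_q` quantile of
one platform's gene totals and at or below the `low_q` quantile of
another's (type-7 quantiles; ≥ / ≤ at the cutoff value — with small gene
panels the convention changes results, so it is stated). Two presets are
shipped, 99th/10th and 90th/10th, because both appear in practice;
neither is anointed. `flag_bias_genes` generalizes to many platforms:
candidates exceed the per-platform 90th percentile in *every* non-focal
platform; candidates whose focal total is below 30 are bias genes, the
rest the comparison group. The absolute 30-count cutoff is
depth-dependent and therefore exposed as a parameter.
`attribute_anova` then tests GC fraction or gene length between the two
groups (one-way ANOVA), and `biotype_summary` tallies biotypes.
`contamination_fraction` is simply the fraction of spots with nonzero
counts of an ambient gene (hemoglobin-style blood contamination).

# The synthetic generator

`simulate_dataset` emulates the statistical structure the analyses
assume, with every draw from one seeded generator in a fixed order:

1. cells are placed uniformly over the capture bounding box and labeled
   by the layout region (`eye_rings` concentric rings or `layers`
   parallel bands);
2. per cell and gene, molecule counts are Poisson at the region's
   program rate (expected molecules per cell);
3. each molecule's capture position is its cell position plus isotropic
   Gaussian noise of s.d. `sigma_diff_um` — the lateral-diffusion model.
   No published generative diffusion model exists for these platforms;
   the Gaussian kernel is this package's modeling choice, and the LWHM
   recovery tests are stated against it;
4. molecules are captured by the nearest spot center if within half the
   spot diameter (molecules landing in dead space are lost; with no
   diameter, capture is always-nearest). Note a radius of `pitch/2`
   does **not** tile a square grid — corners sit at
   `pitch·√2/2` — so full capture requires `diameter ≥ pitch·√2`;
5. each captured molecule gets `1 + Poisson(mean − 1)` reads — the
   shifted Poisson guarantees ≥ 1 read per observed molecule and is the
   simplest duplication model producing non-trivial saturation curves;
6. ambient genes are additionally emitted uniformly over the capture
   area at `rate × contamination_fraction` per 100 × 100 µm.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: PCR sequence bias, barcode swapping,
segmentation errors, anisotropic diffusion along tissue structure, cell
size variation, and spatial autocorrelation of cell density. Parameter
recovery on this generator validates the estimators' correctness, not
any claim about a specific commercial platform.

## Problem sizes and numerical choices

The test and demo scenarios use 200 × 300 to 300 × 300 µm capture areas
at 10 µm pitch (600–900 spots), 2,000–10,000 cells and 30–35 genes —
sizes at which every statistic is estimable with small Monte-Carlo error
while a full suite run stays fast. The diffusion parameter-recovery
check uses a 10 µm marker band (one strip bin wide): with a wider band
the peak bin is decided by noise among equal-expectation bins and LWHM
inherits ±1-bin jitter, while a one-bin band pins the peak and makes the
σ = 0 LWHM exactly half a bin by linear interpolation. Ten paired seed
triplets at σ ∈ {0, 5, 20} µm must give strictly increasing median LWHM
in ≥ 95% of triplets.

The demo benchmark (`demo_config`) simulates two platforms on an
eye-like ring layout (lens / pNR / melanocyte) sharing 10 µm pitch and
differing in diffusion (2 vs 12 µm), capture radius, read depth and
contamination (0.3 vs 0.7). Both platforms share one pitch because the
strip bin width is 10 µm: profiling a 20 µm-pitch array at 10 µm bins
yields comb-like profiles with empty alternate bins, for which LWHM is
meaningless; comparing platforms of unequal pitch requires bins at least
as coarse as the coarsest pitch. The demo's LWHM medians rest on only
three modalities and are accordingly noisy run to run; the dedicated
recovery test with ten seed triplets is the calibrated check.

# Known limitations

* The simulator's uniform cell placement has no spatial clumping, so
  window-sum variances on synthetic data underestimate real-tissue
  variance.
* LWHM on arrays whose pitch exceeds the bin width requires rebinning
  (`bin_spots` or a coarser strip bin); the package does not do this
  automatically.
* The internal DBSCAN is quadratic in expressing spots; for genes
  expressed in tens of thousands of spots a specialized implementation
  would be preferable.
* `expected_umis` uses log-binomial coefficients; for read totals above
  ~10^15 the binomial coefficients lose precision before R's doubles do.

# Reproducibility

Every stochastic function takes a seed and restores the caller's RNG
state. `run_full_benchmark` derives all stage seeds from one master
seed, and reruns reproduce every output file byte for byte — asserted in
the test suite.
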