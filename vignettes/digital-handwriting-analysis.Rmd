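---
title: "Digital handwriting analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital handwriting analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handwritr)
```

# What this package computes

`handwritr` analyses children's handwriting recorded on a pen tablet. A
recording is a 200 Hz stream of pen samples — position (0.25 mm per device
unit), pressure, two tilt angles and a surface-contact flag — collected
while a child copies a short text. From each recording the package
extracts twelve *digital features* spanning four domains:

* **static**: mean space between words (mm); SD of handwriting density
  (points per occupied grid cell);
* **kinematic**: spectral median of the tremor residual; spectral median
  of the pen-down speed series; spectral distance of the speed spectrum
  to the typical child of the same grade;
* **pressure**: in-air time ratio; mean pen pressure; mean and SD of the
  pressure-change speed;
* **tilt**: spectral distance of the tilt-x spectrum to the grade
  reference; tilt-x spectral bandwidth; spectral median of tilt-y.

Downstream, the features feed three analyses: bootstrap linear models of
how each feature tracks handwriting quality and speed across the school
curriculum, a normative diagnosis rule for dysgraphia, and K-means
subtyping of the diagnosed children.

# Feature definitions and their numerical choices

## Shared spectral machinery

Every spectral feature uses one estimator: the one-sided periodogram of
the mean-removed, unwindowed series, with the DC bin excluded
(`power_spectrum()`). All statistics are taken from the *normalized*
spectral distribution, so the periodogram's scale convention cancels.

* `spectral_median()` is the smallest frequency at which the cumulative
  normalized power reaches 1/2. It is a grid value — the resolution is
  `fs / n` — which is why invariance tests compare medians "within one
  frequency bin".
* `spectral_bandwidth()` is the width of the central interval holding
  95% of the power, excluding 2.5% in each tail.
* Spectral distances re-bin both spectra onto a fixed 0.5 Hz grid
  (bins `((j-1)h, jh]`, overflow into the last bin) and take the
  Euclidean distance between normalized power vectors. Re-binning makes
  recordings of different lengths comparable; without it the two
  spectra would live on incommensurate grids.

The per-grade *reference spectra* are the renormalized means of the
rebinned, normalized speed and tilt-x spectra of a typically developing
reference cohort (`build_reference_spectra()`).

## Series construction

* The **speed series** is the distance between consecutive on-surface
  samples divided by their time difference, in mm/s, concatenated
  across strokes (pen-up gaps never contribute a pair). Concatenation
  trades a small amount of spectral leakage at stroke boundaries for a
  single well-populated series; the same convention is applied to every
  child, and the distance features compare like with like.
* The **tremor residual** is the perpendicular deviation of each
  stroke's trace from its 10-sample centered moving-average smooth
  (`stats::filter`, two-sided; for an even window the filter extends
  `w/2` samples forward and `w/2 - 1` backward). Residuals within half
  a window of a stroke edge are trimmed rather than padded.
* **Pressure-change speed** works on consecutive non-overlapping
  buckets of 10 on-surface samples: |difference of bucket mean
  pressures| / (time between bucket centres).
* The **density grid** tessellates the trace bounding box with square
  cells of 300 device units (75 mm² at 0.25 mm/unit), anchored at the
  bounding-box minimum so the feature is translation invariant.

Features whose preconditions fail — too few samples, a degenerate
(zero-power) spectrum, fewer than two words on any line, a grade missing
from the reference — are reported `NA`, never silently zero-filled.

## Word segmentation

Strokes (maximal pen-down runs) are scanned in writing order: a downward
jump of the stroke centre of ≥ 8 mm opens a new line; within a line, a
horizontal bounding-box gap of ≥ 3 mm opens a new word
(`segment_words()`). The thresholds are configuration, not estimated
from data, and assume the left-to-right copying-task layout.

# Cohort-level models

## Normative diagnosis

BHK quality is a degradation score (higher = worse). Its age-normalized
value is `(mean_grade − raw) / sd_grade`; speed, a count of characters
written, normalizes as `(raw − mean_grade) / sd_grade`. Dysgraphia is
diagnosed on quality alone: normalized quality ≤ −2, i.e. a raw score at
least two SDs worse than the grade mean. Under a Gaussian score model
this cutoff captures a ≈ 2.3% tail of the typical population, which the
acceptance tests verify by simulation.

## Bootstrap linear models

For each feature and outcome the package fits
`outcome ~ z(feature) + grade + gender` by OLS (grade numeric 1–5,
gender coded M = 1), optionally adding the `z × grade` interaction whose
coefficient measures how a feature's predictive value changes across the
curriculum. Because BHK residuals need not be normal, inference is a
case-resampling bootstrap over children: BCa 95% intervals per
coefficient and two-sided percentile p values
(`2·min(prop ≤ 0, prop ≥ 0)`, floored at `1/B`). The default is
`B = 10000`; the bootstrap statistic solves the least-squares system by
QR directly, so a full battery stays tractable. If the BCa endpoints are
unavailable (degenerate replicate distribution) the interval falls back
to bootstrap percentiles, and an exactly-constant replicate distribution
collapses to a point interval.

## Subtyping

The dysgraphic subset is clustered with K-means after column z-scoring
(`standardize_matrix()`; Euclidean distance would otherwise be dominated
by the device-unit pressure scale — note this also means a feature
carrying pure noise contributes full weight, so feature curation matters).
The number of clusters is chosen by majority over five indices — elbow
(maximal second difference of the within-SS curve), mean silhouette,
Calinski–Harabasz, Davies–Bouldin, and the gap statistic (first-SE-max) —
ties broken toward the smaller k, winners backed by ≤ 2 indices flagged
low-confidence. Clustering *tendency* is quantified by the Hopkins
statistic under the convention `H = Σw / (Σw + Σu)` (w: data-to-data
nearest-neighbour distances; u: uniform-to-data), so spatially uniform
data gives H ≈ 0.5 and clustered data pushes H *below* 0.5; the opposite
labelling also circulates, so the convention is stated wherever H is
reported. Cluster robustness is a bootstrap Jaccard: resample children,
re-cluster, match original clusters to their best bootstrap counterpart,
average over replicates.

# The synthetic cohort generator

Real clinical recordings cannot ship with the package, so
`simulate_recording()` draws a stylized copying task: letters are
1.25-turn circular loops of 5 mm diameter traversed at a grade-dependent
base speed with sinusoidal speed fluctuation, perpendicular sinusoidal
tremor riding on the trace, pen-up hops between letters, words and
lines, piecewise-linear pressure whose slope resamples at random switch
times, and sinusoidal tilt plus sensor noise. The profile defaults
(`script_profile()`) encode developmental trends — older children write
faster with less tremor — and `simulate_cohort()` layers on a cohort
model: 218 typically developing and 62 dysgraphic children across
grades 1–5, latent severity (0 for TD children, truncated normal ≥ 1 in
the diagnosed group), three planted dysgraphia subtype profiles
(`dysgraphia_subtypes()`), and a linear BHK score model with grade,
severity and gender terms.

**Scope and limits.** The generator emulates the *signal structure* the
features respond to — spacing, spectra, pressure dynamics, pen lifts,
tilt oscillation — not legibility or letterforms. Setting TD severity to
exactly 0 makes the TD quality score Gaussian given grade and gender, so
the −2 diagnosis cutoff has an analytically known tail rate; it also
means the TD/D quality gap is a two-point severity mixture rather than a
continuum. Closed-loop checks (planted tremor frequency recovered,
planted word gaps recovered, constant speed when modulation is off) are
part of the test suite; spectral leakage from concatenating on-surface
segments means the tilt-x *bandwidth* responds less reliably to a second
planted tilt component than the tilt-x *distance* does, which is why the
subtype separation is carried mainly by the distance features.

# Reproducibility

Every stochastic stage — recording simulation, cohort draws, bootstrap,
K-means restarts, gap statistic, stability resampling, Hopkins sampling —
takes an explicit integer seed, and `run_pipeline()` records its seeds in
a manifest. All file formats are plain delimited text with `#key: value`
metadata headers.

```{r example, eval = FALSE}
sim <- simulate_cohort(cohort_spec(), seed = 1)
res <- run_pipeline(sim$cohort, sim$recordings,
                    boot_config = bootstrap_config(1000, 1), seed = 1)
res$demographics
res$models
res$clustering
```
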