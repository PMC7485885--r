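# handwritr

Computational analysis of handwriting acquisition from pen-tablet
recordings: digital feature extraction, normative dysgraphia diagnosis,
bootstrap developmental models, and K-means subtyping — plus a synthetic
pen-trajectory cohort simulator that makes the whole pipeline testable
end to end without clinical data.

## The science

Handwriting difficulties (dysgraphia) affect a substantial fraction of
school-age children. Clinically they are assessed with scales such as
the BHK, which scores a copied text for quality (a degradation score:
higher = worse) and speed (characters written). Digitizing tablets record
what the scales cannot see: the pen's position at 200 Hz, its pressure,
its tilt, and whether it touches the surface. From such recordings this
package extracts twelve *digital features* in four domains:

| Domain | Features |
|---|---|
| static | mean space between words (mm); SD of handwriting density |
| kinematic | spectral median of the tremor residual; spectral median of pen-down speed; spectral distance of the speed spectrum to the grade-typical child |
| pressure | in-air time ratio; mean pressure; mean and SD of pressure-change speed |
| tilt | spectral distance of tilt-x to the grade reference; tilt-x bandwidth; spectral median of tilt-y |

Downstream analyses:

* **Diagnosis** — per-grade norm tables age-normalize BHK scores;
  normalized quality ≤ −2 (raw score ≥ 2 SD worse than the grade mean)
  flags dysgraphia.
* **Developmental models** — for each feature,
  `BHK ~ z(feature) + grade + gender` (optionally with a `z × grade`
  interaction) is fit by OLS with case-resampling bootstrap inference:
  BCa 95% intervals and percentile p values, because BHK residuals need
  not be normal.
* **Subtyping** — the dysgraphic subset is z-scored and clustered with
  K-means; the number of clusters is chosen by majority over five
  indices (elbow, silhouette, Calinski–Harabasz, Davies–Bouldin, gap
  statistic), clustering tendency is checked with the Hopkins statistic
  (convention: uniform ≈ 0.5, clustered < 0.5), and cluster robustness
  with a bootstrap Jaccard stability score.
* **Calibration** — pressure scales differ across tablets; a monotone
  4th-degree polynomial response model maps a source device's pressure
  onto a target device's scale.

Real clinical recordings cannot ship with a package, so `handwritr`
includes a generative model of the copying task itself — loopy letters
traversed at grade-dependent speed with sinusoidal speed fluctuation and
tremor, pen-up hops, piecewise-linear pressure, oscillating tilt — with
planted developmental trends, a linear BHK score model, and three
planted dysgraphia subtype profiles. Every claim the analysis code makes
is tested closed-loop against what the generator planted.

## Worked example

Simulate a small study (15 typical + 8 dysgraphic children, grades 1–5)
and run the full pipeline — feature extraction, norm building, diagnosis,
and the bootstrap model battery:

```r
library(handwritr)

spec <- cohort_spec(n_td_per_grade = rep(3, 5),
                    n_d_per_grade = c(0, 2, 2, 2, 2),
                    n_lines = 2, words_per_line = 3)
sim <- simulate_cohort(spec, seed = 42)

res <- run_pipeline(sim$cohort, sim$recordings,
                    boot_config = bootstrap_config(500, 42), seed = 42)
res$demographics
#> # A tibble: 2 × 8
#>   diagnosed     n males left_handed quality_mean quality_sd speed_mean speed_sd
#>   <lgl>     <int> <int>       <int>        <dbl>      <dbl>      <dbl>    <dbl>
#> 1 FALSE        15     6           3         15.1       3.22       189.     85.4
#> 2 TRUE          8     4           1         29.7       5.19       135.     71.3
```

The diagnosis recovered exactly the planted dysgraphic children:

```r
table(planted = sim$cohort$group, diagnosed = res$cohort$dysgraphia)
#>        diagnosed
#> planted FALSE TRUE
#>      D      0    8
#>      TD    15    0
```

The model battery is a tidy tibble. In-air time predicts quality
degradation strongly once dysgraphic children are included, but not
within the typical group alone:

```r
subset(res$models, term == "z" & outcome == "bhk_quality_raw" &
         form == "main" & feature == "in_air_time_ratio")
#>   feature           outcome         form  dataset term estimate conf.low conf.high p.value  n
#> 1 in_air_time_ratio bhk_quality_raw main  TD      z        2.21    -5.56      8.48   0.496 15
#> 2 in_air_time_ratio bhk_quality_raw main  TD+D    z       12.6      9.88     17.7    0.002 23
```

Features for a single recording:

```r
rec <- sim$recordings[[1]]
rec
#> <pen_recording> child child_001 on sim-tablet: 6041 samples, 30.200 s, fs = 200 Hz, 0.25 mm/unit

extract_features(rec, res$reference, grade = sim$cohort$grade[1])
#> space_between_words           5.104
#> sd_handwriting_density     2901.259
#> median_psd_tremor             8.735
#> median_psd_speed              1.868
#> dist_mean_speed_freq          0.043
#> in_air_time_ratio             0.199
#> mean_pressure               127.872
#> mean_speed_pressure_change   79.706
#> sd_speed_pressure_change    127.693
#> dist_mean_tiltx_freq          0.037
#> bandwidth_tiltx               6.858
#> median_psd_tilty              3.636
```

Recordings and all result tables round-trip through plain delimited text
(`write_recording()` / `read_recording()`, `out_dir =` in
`run_pipeline()`); `autoplot()` methods cover recordings, model
batteries and cluster results.

## Testing

The test suite (testthat 3e) contains per-module unit and property
tests, plus `tests/testthat/test-acceptance.R` with one block per
acceptance criterion: oracle agreement of all twelve features against
loop-based reference implementations on 200 random recordings,
closed-form feature values, invariance laws (translation, time dilation,
pressure scaling), OLS/normal-equation agreement and BCa coverage,
significance-pattern recovery, planted-subtype clustering recovery,
exactness of the diagnosis rule with its normal-tail prevalence, and
quartic calibration recovery. Run it against the installed package:

```r
testthat::test_dir("tests/testthat", package = "handwritr",
                   load_package = "installed")
```

## Design notes

The vignette (`vignettes/digital-handwriting-analysis.Rmd`) documents
every numerical choice: the shared periodogram machinery and its grid
conventions, series construction (speed, tremor residual,
pressure-change buckets, density grid), word segmentation thresholds,
the bootstrap scheme, the k-selection majority rule and Hopkins
convention, and the scope and limits of the synthetic generator.

## License

MIT (see `LICENSE`).
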