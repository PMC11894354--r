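# hrvgaps

Heart-rate-variability (HRV) metrics from wearable interbeat-interval (IBI)
streams, and what missing data does to them.

Wrist smartwatches with photoplethysmography (PPG) sensors can record an IBI
for every detected beat, day and night, for months — but free-living
recordings are riddled with gaps from imperfect wear compliance and motion
artifacts. `hrvgaps` is an R package for researchers who analyse such
streams. It implements:

* **Ingestion and QC** — timestamped IBI and per-minute step-count readers
  (CSV/JSON), artifact removal (IBI < 300 ms or > 1500 ms), wall-clock-aligned
  5-minute windowing, an expected-data-fraction wear-compliance statistic
  (against a nominal 60 beats/min), and a 15-s gap rule that selects the
  longest continuous segment of a window (windows with more than 3 such gaps
  are dropped from frequency-domain analysis).
* **Six HRV metrics per window** — time domain: median IBI, STDRR (SD of the
  IBI values) and RMSDRR (root mean square of successive differences,
  `sqrt(mean((IBI_{i+1} - IBI_i)^2))`); frequency domain: LF and HF power and
  their ratio. The tachogram is resampled to 5 Hz with shape-preserving PCHIP
  interpolation, band-passed to LF (0.04–0.15 Hz) or HF (0.15–1.0 Hz) with a
  zero-phase Butterworth filter, tiled into 60-s (LF) or 30-s (HF)
  sub-windows, and each sub-window scored as `ln(var(x))`; values outside
  [2.5, 9.0] are censored and the median of the survivors represents the
  window.
* **Semisimulation of missing data** — four empirically observed gap
  patterns at nominal 10/20/35/60 % missingness: one 3.15-min burst at the
  window start (60 %), one burst from minute 1.00 to 2.75 (35 %), and
  0.80 min / 0.63 min of scattered 1–2-s dropouts (20 % / 10 %), transplanted
  onto reference windows so that degraded and reference metrics can be
  compared window by window.
* **Statistics** — random-intercept linear mixed models
  (`value ~ level + (1 | participant)`) contrasting each missingness level
  against reference, with Satterthwaite p-values and parametric-bootstrap
  95 % CIs; Box-Cox transforms with profile-likelihood lambda; ICC(2,k)
  agreement and consistency with McGraw–Wong F-based CIs; Bland-Altman
  limits of agreement; RMSE.
* **A synthetic cohort generator** — paired PPG/ECG beat processes with
  configurable LF/HF oscillations, beat noise, artifacts, device bias,
  wear schedules and activity blocks, plus per-window ground truth, so the
  whole pipeline is testable without device data.

## Worked example

```r
library(hrvgaps)
library(dplyr)

cfg <- synth_config(participant_count = 4, duration_days = 6 / 24,
                    activity_blocks = list(c(3600, 10800, 60)), seed = 42)
cohort <- generate_cohort(cfg)

ppg <- cohort$ibi |> filter(participant_id == "P01", device == "ppg")
windows <- ppg |>
  filter_artifacts() |>
  segment_windows() |>
  find_gaps() |>
  classify_activity(filter(cohort$steps, participant_id == "P01"))

participant_inclusion(windows)
#>   participant_id device total_windows usable_windows participant_expected_fraction included
#> 1 P01            ppg               72             72                           100 TRUE

metrics <- compute_hrv(windows)
metrics_table(metrics) |>
  group_by(activity) |>
  summarise(across(c(median_ibi, stdrr, rmsdrr, lf, hf, lf_hf), ~ mean(.x, na.rm = TRUE)))
#>   activity median_ibi stdrr rmsdrr    lf    hf lf_hf
#> 1 light          695.  33.9   28.9  6.39  5.93  1.08
#> 2 rest           893.  34.1   33.3  6.42  5.89  1.09
```

The participant passes the 70 % expected-data-fraction QC with a fully worn
stream (72 windows, all usable). Median IBI near 893 ms at rest and 695 ms
during the 60 steps/min activity block reflects the configured means; LF and
HF are on the censored ln-variance scale (ms², natural log), so 6.4 and 5.9
correspond to band variances of roughly e^6.4 ≈ 600 and e^5.9 ≈ 365 ms².

Degrading the same windows with the built-in patterns and recomputing:

```r
degraded <- degrade_dataset(windows, levels = c(10, 20, 35, 60), seed = 42) |>
  compute_hrv()
metrics_table(degraded) |>
  group_by(level) |>
  summarise(hf = mean(hf, na.rm = TRUE), median_ibi = mean(median_ibi, na.rm = TRUE))
#>   level    hf median_ibi
#> 1    10  5.74       825.
#> 2    20  5.67       827.
#> 3    35  5.89       826.
#> 4    60  5.87       826.
```

The scattered 10 %/20 % patterns depress HF (5.74 and 5.67 against the ~5.9
reference: interpolating across many small dropouts smooths exactly the
high-frequency content), while the single-burst 35 %/60 % patterns leave the
band power of the surviving segment nearly untouched — the central
qualitative finding the statistical stage quantifies. Mixed-model contrasts
and device agreement follow as
`fit_missingness_contrasts(...)` / `agreement_analysis(align_devices(...))`,
or in one step over a full synthetic cohort:

```r
res <- run_pipeline(pipeline_config(), out_dir = "run1")
```

which writes `qc.csv`, `metrics_reference.csv`, `metrics_degraded.csv`,
`contrasts.csv`, `agreement.csv` and a `manifest.json` reproducibly under
the configured seed.

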