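---
title: "HRV from wearable IBI streams under missing data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV from wearable IBI streams under missing data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvgaps)
```

`hrvgaps` quantifies two things about heart-rate-variability (HRV) metrics
computed from wearable interbeat-interval (IBI) streams: how stable each
metric is when realistic fractions of the stream are missing, and how well a
wrist photoplethysmography (PPG) device agrees with a chest ECG reference.
This vignette is the package's own account of the underlying procedure, its
assumptions, the tunable parameters, and the places where the design was
genuinely open.

## The measurement model

A stream is a sequence of `(timestamp, IBI)` pairs, milliseconds since epoch
and milliseconds per beat. Values above 1500 ms or below 300 ms are treated
as detection artifacts and removed before any analysis; the inequalities are
strict, so boundary values are retained. Streams are partitioned into
**wall-clock-aligned 5-minute windows** (`floor(t / 300000)`), so windows
from different devices and participants line up exactly in real time — the
property the between-device comparison relies on.

Wear compliance is scored by the **expected data fraction**: the observed
IBI count divided by a nominal 300 points per window (60 beats/min), as a
percentage capped at 100 (a faster heart rate yields more than 300 beats;
the cap keeps the statistic in [0, 100]). At the participant level the
denominator counts *all* 5-minute slots between the first and last observed
window — empty slots included, since non-wear is exactly what the statistic
must detect — and participants below 70 % are excluded by default.

### Time-domain metrics

Per window, over all its samples: median IBI, `STDRR` (sample SD of the IBI
values) and `RMSDRR = sqrt(mean(diff(IBI)^2))` (the RMSSD of the HRV
literature). At least 2 samples are required (`time_valid` flag otherwise).

### Frequency-domain metrics

The path to LF/HF power is where gap handling matters:

1. **Gap rule.** A gap is a consecutive-timestamp difference strictly above
   15 s. The intervals from the window start to the first sample and from
   the last sample to the window end count too: a burst of missing data at
   the start of a window — the dominant real-world pattern — must register
   as a gap. A window with more than 3 gaps (or fewer than 2 samples) is
   unusable for frequency analysis; otherwise the **longest continuous
   segment** between gaps (earlier one on ties, for determinism) is used.
2. **PCHIP resampling to 5 Hz.** Shape-preserving piecewise cubic Hermite
   interpolation through the segment's samples on a uniform 200-ms grid.
   PCHIP reproduces the samples exactly and cannot overshoot between knots,
   which matters because overshoot would manufacture spurious band power.
   The segment is defined in wall-clock terms and includes the window edges
   whenever the edge gap is within the 15-s threshold; across such
   sub-threshold edge stretches the boundary value is held constant
   (implemented as hold-value pseudo-knots) rather than extrapolated with a
   cubic, which keeps the no-overshoot guarantee. A gap-free window thus
   yields exactly 1500 samples — 5 complete 60-s sub-windows and 10
   complete 30-s sub-windows below. Segments shorter than 60 s (one LF
   sub-window) or with fewer than 4 samples are refused (`freq_valid`
   flag).
3. **Band filtering.** The resampled signal is demeaned and filtered to
   LF (0.04–0.15 Hz) and HF (0.15–1.0 Hz). The HF upper edge is 1.0 Hz
   rather than the conventional 0.40 Hz so that breathing rates during
   physical activity stay in band. The realization is a 4th-order
   Butterworth band-pass applied forward-backward (zero phase), so filter
   delay cannot shift energy across the sub-window boundaries of the next
   step. Tests assert tone gains against the filter's own analytic
   frequency response, not a specific coefficient set.
4. **Censored ln-variance.** The filtered signal is tiled into consecutive
   non-overlapping sub-windows — 60 s for LF, 30 s for HF; a partial
   trailing sub-window is discarded — and each sub-window is scored
   `ln(var(x))` with the population variance in ms². Scores below 2.5 or
   above 9.0 are eliminated (a zero-variance sub-window gives `-Inf` and is
   censored by the same rule), and the **median of the survivors**
   represents the window; no survivors means no estimate. LF/HF is the
   ratio of the two median ln-powers, consistent with resting values near
   LF ≈ 6.5, HF ≈ 5.5, LF/HF ≈ 1.2 on this scale.

Failures at any step set validity flags rather than raising errors, so a
cohort run always completes.

## Semisimulated missing data

Rather than deleting beats at random, the degradation stage transplants gap
layouts observed in genuinely sparse windows onto clean reference windows —
a *semisimulation*. Four built-in patterns are indexed by nominal
missingness level:

| level | kind    | layout                                   | total removed |
|-------|---------|------------------------------------------|---------------|
| 60 %  | burst   | one gap covering the first 3.15 min      | 3.15 min      |
| 35 %  | burst   | one gap from minute 1.00 to minute 2.75  | 1.75 min      |
| 20 %  | scatter | 1–2-s dropouts at random offsets         | 0.80 min      |
| 10 %  | scatter | 1–2-s dropouts at random offsets         | 0.63 min      |

Patterns are defined by **removed duration, not removed point count**: the
level labels are nominal (on evenly spaced beats the "60 %" burst removes
63 % of the points), and duration is the only reproducible description of
an observed gap layout. Scatter gap lengths are uniform on [1, 2] s with the
final gap trimmed so the total is exact; placement is sequential uniform
with overlap rejection (0.5-s separation so adjacent dropouts cannot merge),
deterministic under the seed. One pattern instance per level is reused
across all windows, mirroring how an observed sparse window's layout is
matched onto each reference window; per-window re-randomised scatter is
available (`rerandomize_scatter`) for sensitivity analysis but off by
default. Applying a pattern is a pure filter — surviving samples are
bit-identical — and the bursts trigger exactly one >15-s QC gap while the
scatter patterns trigger none, which is precisely why the two regimes affect
the metrics so differently.

## Statistical stage

**Missingness contrasts.** Per metric and activity class (rest =
mean steps exactly 0; light = mean steps in (0, 100); at least 2 step
records per window, else unknown), the long table of window values is fit
with a REML linear mixed model `value ~ level + (1 | participant)`, the
reference level as baseline. Each level's contrast is reported with its SE,
a two-sided p-value using Satterthwaite denominator degrees of freedom, and
a percentile 95 % CI from a parametric bootstrap (simulate from the fitted
model, refit, 1000 replicates by default) — `lme4`/`lmerTest` provide the
machinery; the package's contribution is the pipeline that feeds them.
Metrics far from normal are Box-Cox transformed first, with lambda chosen
by profile likelihood on a refined grid. Because visual Q-Q inspection is
not reproducible in code, the default bookkeeping is an explicit map —
STDRR and RMSDRR at rest, RMSDRR and LF/HF at light activity — with an
automated |skewness| > 0.5 rule as fallback for unmapped pairs, and
`qq_points()`/`plot_qq()` for the visual check. Estimates for transformed
metrics are on the transformed scale, which is why contrast magnitudes
differ by orders of magnitude across metrics.

**Agreement.** PPG and ECG metric tables are inner-joined on
`(participant, window start)` — real-time alignment again — and each metric
is summarised by ICC(2,k) (two-way random effects, mean of k = 2 raters)
for *consistency*, `(MS_R − MS_E)/MS_R`, and *absolute agreement*,
`(MS_R − MS_E)/(MS_R + (MS_C − MS_E)/n)`, with McGraw–Wong F-based 95 % CIs
(the agreement interval uses a Satterthwaite df on the single-rater ICC and
a Spearman–Brown step-up); plus Bland-Altman mean difference with
`±1.96·SD` limits of agreement, and RMSE. ICC magnitudes above 0.5 / 0.75 /
0.9 are labelled moderate / good / excellent. The ICC is implemented
directly from the two-way ANOVA mean squares and cross-checked in the test
suite against an independent `aov()`-based computation.

## The synthetic cohort generator

No public dataset of months-long wrist IBI streams exists, so the package
carries a generator whose defaults describe the kind of cohort the analyses
target: 16 participants, 14 days, resting mean IBI 889 ms and light-activity
mean 691 ms, an LF oscillation at 0.10 Hz (amplitude 35 ms) and an HF
oscillation at 0.25 Hz (amplitude 25 ms) — amplitudes chosen so clean-window
ln-variance powers land near 6.5 (LF) and 5.5 (HF) — beat-to-beat Gaussian
noise of 10 ms, a 0.1 % artifact rate drawn uniformly from
[100, 300) ∪ (1500, 3000] ms (exercising both filter bounds), PPG
measurement noise of 10 ms with a +5 ms bias (yielding imperfect but
positive device agreement, so the ICC machinery is exercised away from its
fixed points), and one daily 2-hour 60 steps/min activity block.

Beats are emitted iteratively — next beat time = previous time + current
IBI, with the IBI evaluated from the activity-dependent base level plus the
two sinusoids plus noise at the current time — the simplest generative model
with controllable band content. Activity switches the base IBI with a 30-s
linear ramp, avoiding step discontinuities that would register as spurious
HF power. Artifacts replace the *recorded* value only, leaving beat timing
intact, as real detection glitches do. PPG and ECG streams of a participant
share the same beat process and differ only by device noise and bias.
Everything is deterministic given `(seed, participant, device)`.

What the generator does **not** emulate: physiologically coupled LF/HF
dynamics (baroreflex feedback, respiratory sinus arrhythmia varying with
breathing), circadian modulation, heavy-tailed or autocorrelated artifact
bursts from motion, and missingness that correlates with daily routine.
Passing tests therefore demonstrate that the *pipeline arithmetic* is
correct and that the *directional* missingness effects (smoothing of HF by
scattered dropouts; robustness of median IBI to bursts) are real
consequences of the processing chain — they do not certify effect sizes on
any particular device or population.

## Numerical choices and degenerate inputs

* Expected points per window fixed at 300; fractions capped at 100.
* Duplicate timestamps on ingestion: keep the first, warn — deterministic
  and loggable.
* Time-domain metrics use all in-window samples; only the frequency domain
  is restricted to the longest continuous segment, since interpolation is
  the step a gap corrupts.
* Population variance (divide by n) inside the ln-variance score; sample
  variance (n − 1) for STDRR and the Bland-Altman SD, the respective field
  conventions.
* Equal-length segment ties break to the earlier segment; `which.max` makes
  this explicit.
* Zero-variance sub-windows produce `-Inf` and are censored, never
  propagated.
* Box-Cox demands strictly positive input and says so, rather than silently
  shifting.
* Constant ICC input (zero between-subject variance) yields a flagged `NA`,
  not a division error.

## Problem sizes used by the test suite

The property and acceptance tests run on sizes chosen to exercise every code
path at desk scale: tone cohorts of 30–60 minutes per stream; ~200 rest
windows (4 participants × 4.2 h) for the directional missingness check;
100 simulated cohorts of 16 participants × 50 windows per level for
fixed-effect bias and 50 cohorts of 16 × 10 windows with 150
parametric-bootstrap draws for CI coverage. These sizes are the package's
own trade-off between statistical resolution and a test suite that runs in
minutes; the pipeline itself scales to months-long cohorts limited only by
the mixed-model stage (the bootstrap dominates, linear in `n_boot`).

## Known limitations

* The 5-Hz resampling rate, band edges, sub-window lengths and censoring
  bounds are exposed as parameters but have been exercised mainly at their
  defaults.
* The scatter patterns' exact gap coordinates are seeded-random by
  construction; only their totals and length range are empirically
  anchored.
* LF/HF is a ratio of two ln-scale medians, so it is *not* the log of the
  classical band-power ratio; compare like with like across studies.
* With only two devices, ICC(2,k) is ICC of the mean of two raters;
  single-rater agreement would be lower.
* High-activity windows (≥ 100 steps/min) are classified but excluded from
  the standard contrasts; short high-intensity bouts need shorter windows
  than 5 minutes, which the frequency-domain method cannot support.
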