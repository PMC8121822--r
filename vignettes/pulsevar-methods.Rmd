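---
title: "Methods: comparing pulse rate variability with heart rate variability across blood-pressure states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing pulse rate variability with heart rate variability across blood-pressure states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsevar)
```

## The question and the model

Heart rate variability (HRV) is measured from the time differences between
consecutive ECG R peaks; pulse rate variability (PRV) from the time
differences between consecutive photoplethysmographic (PPG) pulse onsets.
Each pulse onset trails its R peak by one pulse transit time (PTT). If PTT
were constant, every pulse-to-pulse interval would equal the corresponding
R-to-R interval and PRV would be HRV exactly — a constant shift cancels in
differences. The degree to which PRV deviates from HRV is therefore a
question about PTT *variation* and about the measurement chain (sampling
quantization, fiducial-point detection, outlier handling).

`pulsevar` models this directly. The interbeat interval process is

RR(t_i) = μ + A_LF·sin(2π f_LF t_i) + A_HF·sin(2π f_HF t_i) + ε_i,

with ε_i ~ N(0, σ²_RR), and the pulse onset stream is the R stream shifted
by PTT_i = μ_PTT + η_i, η_i ~ N(0, σ²_PTT) i.i.d. per beat. Under this model
the successive-difference variance of the pulse intervals exceeds that of
the R intervals by 6σ²_PTT (each PP difference contains the second
difference of three independent PTT draws), so short-term indices — RMSSD,
SD1 = RMSSD/√2, the HF band power — are *systematically overestimated* by
PRV while slow indices (AVNN, the LF trend component of SDNN) are barely
touched. The package's pipeline makes this propagation measurable end to
end, and its statistics layer quantifies it the standard way: Bland–Altman
bias and limits of agreement on x = HRV − PRV, and the ratio of agreement

BAR = 100 · |1.96 σ_x / mean(HRV + PRV)| %,

categorized good (BAR ≤ 10 %), moderate (10 < BAR ≤ 20 %), insufficient
(BAR > 20 %). The category boundaries are taken inclusive at 10 and 20; a
pair with zero bias and zero spread is reported as *total* agreement (this
happens for count-valued indices such as NN50 on quiet series, where both
sources return identical integers).

## Pipeline stages and their parameters

**ABP quality gate.** Records shorter than 5 min are discarded. Cardiac
cycles are delimited by onsets from a slope-sum transform with an adaptive
threshold (half the median of the positive slope-sum mass — a median, not a
high quantile, so artifact-inflated tails do not starve detection) and a
0.27 s refractory period (25–220 bpm). Each cycle gets six quality features:
pulse pressure, duration, mean absolute first difference, skewness, number
of local maxima, and the fraction of samples at the record's clip rails.
Features are standardized robustly — deviation from the per-feature median
in units of max(MAD, floor) — rather than z-scored, because a majority-clean
record should define the reference frame even when artifacts dominate the
variance. The floors have two parts: absolute scales (1 mmHg pulse
pressure, 0.05 s duration, 1 local maximum, …) and relative scales (15 % of
the median for the amplitude-tracking features, 5 % otherwise). The wider
relative floor on pulse pressure and slope magnitude is deliberate: those
features track blood-pressure state, and a record that legitimately crosses
states must not have its hypertensive half declared "poor quality". If no
cycle deviates from the median by more than a norm of 8 there is no
poor-quality subpopulation and all cycles are labelled good; otherwise
k-means with k = 2 (10 restarts, seeded) splits the cycles, the larger
cluster is labelled good, and an exact size tie goes to the cluster with
the larger mean pulse pressure (clean arterial pulses have substantial
pulse pressure; flat-lines have none). The record is accepted when
R_GQ = 100·n_GQ/(n_GQ + n_PQ) ≥ 80 %. The gate operates per record, not per
segment.

**Blood-pressure labelling.** ABP is lowpass filtered (fourth-order
Butterworth, 12 Hz cutoff, forward–backward with mirror padding so the
zero-phase pass has no edge transient). Per-cycle maxima/minima become
systolic/diastolic knots; knots outside 20–300 mmHg or more than 30 mmHg
from the median of their five neighbours are dropped (values chosen so a
single spike artifact cannot bend the trend by more than ~2 mmHg); natural
cubic splines give per-sample SBP/DBP trends. States: hypertension when
SBP > 140 mmHg or DBP > 90 mmHg; hypotension when SBP < 90 or DBP < 60 —
strict inequalities, as the thresholds are conventionally quoted. When both
rules fire on one sample the label is hypotension, the more safety-critical
condition in ICU monitoring. Segment labels are modal; a two-way tie breaks
toward the non-normotensive candidate, and a hypo/hyper tie toward
hypotension.

**Beat detection.** R peaks: derivative–squaring–moving-window-integration
with an adaptive threshold, 250 ms refractory period, and refinement to the
local ECG maximum. PPG onsets: per pulse, the intersection of the tangent
at the maximum-slope point of the rising edge with the horizontal tangent
through the preceding valley, clamped to [valley, max-slope]; a flat edge
falls back to the valley and is flagged. On clean synthetic records both
detectors recover ground truth within one sample at 125 Hz.

**Interval processing.** NN intervals in milliseconds; outliers (outside
mean ± 1.96 SD of the *uncorrected* series, bounds computed once) are
replaced left-to-right by the mean of the five previous already-corrected
values (fewer if fewer exist; the series median if none). The rule is
applied to the raw NN series, then the series is interpolated (natural
cubic spline, knots at each interval's ending beat time, uniform 4 Hz grid
anchored at the first knot, no extrapolation), and the rule is applied once
more to the interpolated series — raw first, interpolated second, one pass
each. Anchoring the grid at the first knot rather than absolute time makes
the interpolation invariant to a pure time shift of the beats, which is
what makes the zero-jitter PRV ≡ HRV equivalence exact.

**Indices.** Time-domain and nonlinear indices use the raw corrected NN
series; spectral indices use the 4 Hz interpolation. The periodogram is
normalized so total power equals the sample variance (Parseval, exact by
construction). Bands: VLF 0.0033–0.04 Hz, LF 0.04–0.15, HF 0.15–0.40, TP
0.0033–0.40; nLF = LF/(TP−VLF) and nHF = HF/(TP−VLF) (the standard
normalization); spectral entropy is the base-2 Shannon entropy of
normalized bin powers over the total band; band centroids treat the
spectrum as the plane region under the curve (cX power-weighted mean
frequency, cY = ΣP²/2 / ΣP). Poincaré SD1 uses the uncentered RMS about the
identity line so SD1 = RMSSD/√2 holds to machine precision. ApEn/SampEn use
m = 2, r = 0.2·SDNN; multiscale entropy sums SampEn over coarse-graining
scales 1–5 with r fixed from the original series (a 5-min series leaves
≥ 60 points at scale 5); base-scale entropy uses 4-point windows, a
4-symbol deviation alphabet, and base scale 0.2·mean|ΔNN|; sign-series
entropy uses length-3 words of difference signs. D2 (Grassberger–Procaccia)
and LYA (Rosenstein) use embedding dimension 10, delay 1, Theiler window
10; D2 fits log C(r) between the 10th and 50th distance percentiles, LYA
fits mean log divergence over the first 10 beats. These hyperparameters are
frozen, not optimized. DFA-1 fits α1 over box sizes 4–16 and α2 over
16–64, after dividing F(n) by the exact finite-size factor √(1 − 4/n²) of
linear detrending — without it the small-box slope of uncorrelated noise is
biased upward by about 0.08.

**Segmentation and orchestration.** Records are cut into 5-min windows
with 10 s overlap between consecutive windows (stride 290 s); the
alternative reading — a 10 s stride — would make consecutive windows 96.7 %
redundant and inflate segment counts ~29-fold, which is not a sensible
sampling design. `run_study()` chains gate → segmentation → labelling →
dual-source series → indices → statistics with full exclusion accounting;
all randomness is seeded, and identical inputs and seed give byte-identical
reports. Kruskal–Wallis post hocs use unpaired rank-sum tests between
states (segments in different states are different epochs, not pairs),
Bonferroni-multiplied by 3 and clipped at 1, and are run only when the
omnibus p < 0.05. The two-treatment Friedman comparison returns p = 1 when
every block ties (the tie-corrected statistic is undefined there).

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* of ICU waveform data: 125 Hz
co-sampled channels, ≥ 5-min records, LF/HF interval modulation, a variable
PTT coupling PPG to ECG, scheduled SBP/DBP excursions across the three
states with 5 s linear ramps, and injectable flat-line/saturation/spike
artifacts with an exact artifact log. The cohort generator draws
between-subject parameters log-normally, calibrated once against the
depressed, right-skewed variability of critically ill adults: measured
through the full detector chain, a 60-record cohort gives RMSSD
11.1 ± 5.8 ms and SDNN 13.5 ± 10.3 ms, matching the ICU scale (roughly
10 ± 6 and 13 ± 10 ms) on both level and spread. PTT jitter defaults to
5–10 ms SD per record, i.i.d. Gaussian per beat.

Deliberately *not* modelled: pathology-specific waveform morphology,
respiration (and hence respiratory PTT modulation — real PTT variation is
partly oscillatory, not white), ectopy and arrhythmia, sensor motion
artifacts on ECG/PPG (artifacts are injected on ABP only, where the quality
gate operates), and cross-record nonstationarity beyond the BP schedule.
Consequences worth stating: the waveform templates are analytic (Gaussian
QRS; a linear-rise/exponential-decay pulse whose tangent intersection
recovers the true foot sub-sample; a smooth gamma-like arterial pulse that
survives 12 Hz filtering unchanged), so detector accuracy here is an upper
bound on real-data accuracy, and passing ground-truth-recovery tests shows
the chain is *correct*, not that it is robust to every failure mode of
bedside data. Likewise the i.i.d. jitter model concentrates the PRV excess
in short-term indices; oscillatory PTT would redistribute some of it into
the LF/HF bands.

## Numerical choices and degenerate inputs

A constant interval series short-circuits the outlier rule (float noise in
accumulated beat times is not dispersion), yields zero SDs, zero Poincaré
dispersions, zero entropies, D2 = 0, and a missing Lyapunov exponent. A
flat ABP or ECG raises explicit "no cycles"/"no peaks" errors. Indices
whose preconditions fail (MSE under 200 intervals, ApEn/SampEn under 60,
α2 when the series cannot fill two 64-boxes, LF/HF with zero HF power,
centroids of empty bands) return NA markers and never abort the rest of the
set. Zero-variance inputs to the Spearman correlation return NA; a constant
vector fails the Lilliefors screen by definition (p = 0). The PTT shift of
the pulse stream perturbs float beat times by ~1 ulp, so the zero-jitter
equivalence is asserted at 10⁻⁹ (and at 10⁻³ for D2/LYA, whose fit-radius
selection through distance quantiles amplifies ulp-level perturbations);
count-valued indices remain bit-identical.

## Problem sizes

The test suite and the acceptance script run on desk-scale inputs chosen as
the package's own study conditions: 5-min records (about 400 beats) for all
waveform-level checks, a 50-subject single-segment cohort for the agreement
pattern, 20 seeds for the DFA limits, 50 seeds for stochastic ordering
properties, and exhaustive 2¹⁰ permutation enumeration for the Friedman
oracle.

## Known limitations

* The quality gate's deviation-norm threshold (8) and the SQI floors were
  set against synthetic clean/corrupted contrasts; bedside ABP with drifting
  baselines may need different floors.
* Under the package's study conditions (PTT jitter 5–10 ms at 125 Hz), the
  pooled BAR for RMSSD/SD1 sits near the moderate/insufficient boundary
  (~18–19 %): the 8 ms quantization floor inflates both sources' RMSSD and
  compresses the relative spread of their difference, and the 1.96 SD
  outlier rule trims the jittered tail further. Stronger or oscillatory PTT
  variation pushes the category to insufficient.
* VLF on 5-min segments is length-limited and retained only for
  completeness; D2 and LYA on 5-min interval series are rough, unoptimized
  estimates and should be compared between sources, not interpreted
  absolutely.
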