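---
title: "Mechanocardiogram analysis: models, parameters and design choices"
author: "mcgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanocardiogram analysis: models, parameters and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcgtools)
```

## The measurement and its analysis

A cluster of stem-cell-derived cardiomyocytes (an embryoid body, EB) beats
spontaneously; an AFM cantilever resting on it converts each contraction
into a force-time pulse of tens to hundreds of nanonewtons. The recording —
a *mechanocardiogram* — is analysed like an ECG read out mechanically: each
contractive event has an R peak (maximum deflection) followed by an S peak
(minimum deflection). From the event series we derive, per recording,

* **contraction force** — the per-beat peak-to-peak amplitude
  $f_R - f_S$ in nN (the inotropic readout),
* **beat rate** — $60 / \overline{RR}$ in bpm, where
  $RR_i = t_{R,i+1} - t_{R,i}$ (the chronotropic readout), and
* **beat-rate variability** — the standard deviation of successive RR
  differences, $\mathrm{SDSD} = \mathrm{sd}(RR_{i+1} - RR_i)$, plus the
  Poincaré descriptors $SD1 = \sqrt{\mathrm{var_{pop}}(\Delta RR)/2}$ and
  $SD2 = \sqrt{2\,\mathrm{var_{pop}}(RR) - \mathrm{var_{pop}}(\Delta RR)/2}$
  (the arrhythmia readout).

Treatment effects are quantified as *relative responses*: a treated
recording's value divided by the same recording's drug-free baseline value
(controls: by the control-group mean), which cancels the very large
cluster-to-cluster differences in absolute force. Group comparisons use
ordinary one-way ANOVA with Holm-Šídák pairwise adjustment, Welch/
Brown-Forsythe ANOVA with Games-Howell pairs when spreads differ, or
Kruskal-Wallis with Dunn's rank tests; concentration series are summarised
by an OLS slope on log10 molar concentration with a Wald t test. Arrhythmic
pauses are counted against a 3 s RR cut-off (strict inequality) and
compared between pooled groups with the Yates-corrected chi-square.

## Choices with scientific content

Several points are under-determined by the assay itself; the package fixes
them explicitly:

* **Fiducial point.** RR intervals are measured R-peak to R-peak. The R/S
  naming is ECG-style; here R is the contraction maximum and S the
  following relaxation undershoot minimum.
* **Contraction force** is peak-to-peak ($f_R - f_S$), not R-to-baseline.
* **Median-ratio RR filter.** "Deviating from the median by more than two
  times" is applied as a two-sided ratio band
  $[\tilde{RR}/2,\; 2\tilde{RR}]$: a one-sided reading would never remove
  pathologically short intervals from double-detected beats. The median is
  taken once, on the raw series. Removing an interval breaks the chain of
  successive differences — pairs are only formed between intervals that
  were adjacent in the raw series and both kept, so the filter cannot
  fabricate artificial differences.
* **SDSD divisor.** Reported SDSD uses the sample ($n-1$) divisor;
  the population divisor appears only inside the $SD1$ identity
  $SD1 = \mathrm{SDSD_{pop}}/\sqrt{2}$, which the tests verify to 1e-12.
* **Validity screen.** Recordings unusable for variability analysis are
  excluded by rule rather than by manual curation: at least 3 raw RR
  intervals above 3 s, or more than 20% of intervals removed by the
  median filter, invalidates a sample. These defaults are documented
  operating points, not claims about any particular manual workflow.
* **Cut-off counting** runs on the *raw* RR series (before the median
  filter): long pauses are the signal there, and the filter would remove
  them. Counts are pooled per treatment group across recordings;
  per-recording counts remain available for sensitivity checks.
* **Concentration axis.** The dilution series is 10-fold spaced
  (10 nM-10 µM), so the regression defaults to log10 molar; a linear
  option is retained.
* **Outlier handling.** A 5-MAD flagging rule (falling back to the 1.5 IQR
  fence when the MAD degenerates) replaces proprietary outlier procedures;
  flags propagate to reports and nothing is deleted silently.
* **Beat rate as 60/mean(RR)** rather than event count per duration, so a
  long pause lengthens the mean RR coherently with the RR-based analyses.

## The synthetic-data generator

Because no public instrument recordings accompany this analysis chain, the
package ships a generator whose defaults encode the study conditions: one
recording phase is 600 s (a 10-minute measurement), sampled at 1000 Hz
(the acquisition rate is an artifact choice — instrument rates vary and
only enter through timing resolution), a base rate of 30 bpm typical of
EBs, 100 nN peak-to-peak amplitude, RR coefficient of variation 0.05,
1 nN additive white noise. Drug action enters multiplicatively:
`inotropy_factor` on amplitude, `chronotropy_factor` on rate,
`variability_factor` on the RR CV, plus per-beat pause injection
(`pause_prob`, pauses uniform on 3.5-8 s so every injected pause exceeds
the 3 s cut-off).

The RR process is i.i.d. truncated normal (±20% of the mean): SDSD is
memoryless, so an autocorrelated RR model would add realism the analysed
statistics cannot see; an AR(1) extension would be straightforward but is
deliberately not a default. The truncation also guarantees that, below a
mean RR of 2.5 s, no ordinary interval can reach the 3 s cut-off — every
counted pause is an injected one, which is what makes the generator's
bookkeeping (`n_pauses`) an exact oracle.

Each beat is rendered as a biphasic pulse built from three raised-cosine
lobes on compact support: a rise lasting `2 * pulse_up_s` to the R maximum
(70% of the swing), a fall to the S minimum (-30%), and a recovery lasting
`2 * pulse_down_s`. The fall duration is set so the curvature left and
right of the R peak matches, making the peak locally symmetric; the
peak-to-peak amplitude then equals the configured value exactly, and peak
localisation is not biased by the pulse shape. Exponential-tailed pulses
were considered and rejected: their cusp peaks make sub-sample timing
noise-limited and their infinite tails leak into neighbouring beats.
Between-recording biology is modelled in `simulate_experiment()` as a
log-normal per-recording amplitude scale (CV 0.25, shared by the two
phases of a recording — realistic for EB clusters whose absolute force
varies severalfold), which baseline normalisation must cancel; baseline
phases reset all drug factors to 1 and the pause probability to 0.

What the generator does **not** emulate: instrument artifacts (cantilever
resonance, contact loss), non-linear baseline wander (only linear drift),
beat-morphology changes under drugs (only amplitude/rate/variability
scale), RR autocorrelation, and ectopic extra beats. Passing tests
therefore demonstrate that the analysis chain recovers known effects from
signals with the *statistical* structure of these recordings — not that it
is robust to every failure mode of a live instrument.

## Numerical choices in the signal chain

* **Detrending.** A rolling-median baseline (default window 10 s, at least
  three beat periods) is estimated on a ~50 Hz decimated copy of the trace
  and interpolated back — the median of a 10 s window changes negligibly
  under 20-fold decimation, and this keeps 10-minute, 1 kHz traces cheap.
* **Noise scale.** The detection threshold is `threshold_k` (default 4)
  times the robust noise scale estimated as
  $\mathrm{MAD}(\Delta f)/\sqrt{2}$ on the first-differenced trace.
  The MAD of the trace itself fails in both directions: pulses inflate it
  once beats occupy most of the recording (the threshold can then exceed
  the R peak), and on a beat-free trace the smoothed noise crosses a
  4-MAD-of-the-smoothed-signal threshold at a substantial Rice rate.
  Differencing suppresses the smooth pulse content and isolates the noise
  floor at any beat rate.
* **Peak finding.** Candidates are local maxima of a 50 ms moving average
  (reflection-padded so edge variance stays flat; a guard band of one
  smoothing width excludes detrending edge artifacts), with plateau ties
  resolved to the earliest sample. Refractory conflicts (< 0.25 s) are
  resolved greedily by descending height, which makes the detected count
  monotone non-increasing in the threshold.
* **Sub-sample timing.** Each R-peak time is refined by a least-squares
  parabola over ±0.12 s of the raw trace; the vertex localises the rounded
  contraction peak with sub-millisecond jitter where a raw argmax wanders
  by several milliseconds under noise. Degenerate fits (non-concave,
  vertex outside the window, clipped by the trace edge) fall back to the
  candidate sample.
* **Peak forces** are measured as ±4 ms local means of the raw trace at
  the peak locations — immune to the positive bias of a noisy maximum and
  to smoothing attenuation.
* **Degenerate inputs.** Empty or flat traces yield zero events (not an
  error); fewer than two events flags the recording as insufficient and
  excludes it from rate/RR statistics; a perfectly constant regression
  reports slope 0 with p = 1, a perfect non-zero fit p = 0; a zero margin
  in the 2x2 cut-off table marks the test "not applicable" instead of
  dividing by zero.
* **Determinism.** One master seed; per-recording, per-phase sub-seeds are
  derived by a fixed string hash, so any subset of an experiment is
  reproducible in isolation and identical configuration + seed reproduces
  every output file byte for byte.

## Problem sizes used by the test suite

The validation suite exercises the chain at sizes chosen to make Monte
Carlo conclusions stable while keeping a full run inside a coffee break:
detector recovery uses 100 recordings of 60 s at 1 kHz (noise-to-amplitude
1%); effect recovery uses 100 replicate experiments of 15 recordings per
arm (40 s at 200 Hz — at 30 bpm, amplitude estimates from ~19 beats per
recording are already tight); the null calibration of the cut-off test
uses 500 replicate two-arm experiments at equal pause rates; the
zero-effect slope calibration uses 400 replicates so that the binomial
error on the observed non-significant fraction (~1%) cannot mask a
mis-calibrated test. Recovery tolerances (e.g. mean relative force
response within [1.3, 1.5] for a 1.4x effect) reflect these sizes.

## Known limitations

* At beat rates above ~45 bpm the pulse support (~1.36 s at default time
  constants) approaches the RR interval and consecutive pulses begin to
  overlap; amplitudes then read slightly low. The defaults keep a 30%
  margin.
* The S-peak time is reported at sample resolution (only R peaks get
  sub-sample refinement); S timing enters no downstream statistic.
* `relative_response()` requires a complete baseline/treatment pairing per
  recording; recordings losing one phase (e.g. detection failure) drop out
  of the dose-response statistics with a warning rather than being
  imputed.
* The Games-Howell and Dunn procedures are implemented from their standard
  formulas and verified against an independent reference implementation
  and against their two-group limiting cases; exotic designs (heavy ties,
  groups of 3) inherit the usual small-sample caveats of those procedures.
* The cut-off test pools RR counts per group; recordings contributing more
  intervals weigh more. Per-recording counts are emitted for sensitivity
  analysis but no hierarchical model is fitted.
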