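---
title: "ThermoClock: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ThermoClock: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoClock)
```

ThermoClock quantifies how ambient temperature is encoded by the Drosophila
circadian circuit, at three levels: behavior (sleep and locomotor activity
under temperature shifts), physiology (GCaMP calcium responses to
temperature steps and their circadian gating), and anatomy (connectome
partner ranking). Because raw recordings of this kind are rarely deposited,
the package ships a synthetic-data generator with planted, recoverable
parameters; every analysis stage is validated by recovering what was
planted. This vignette describes the models, the defaults and why they were
chosen, and what the synthetic validation does and does not establish.

## Behavior: sleep scoring and the four indices

Locomotion arrives as movement counts per 10-s epoch (8640 epochs per
fly-day), the sampling used by camera-based monitors. Sleep follows the
field-standard immobility rule: any run of epochs with counts at or below
the inactivity threshold (default 0) lasting at least `min_bout_min`
(default 5 min, i.e. 30 epochs) is a sleep bout, and every epoch inside a
bout is asleep. Both knobs are exposed because video trackers differ in
their movement-detection thresholds. Sleep and wake minutes always sum to
1440 per fly-day; `scoreSleep()` is checked against an independent
brute-force run-length scanner on random sequences.

Activity and sleep are summarized in 30-min bins (counts summed, sleep
minutes totaled). All windows are half-open `[start, end)` in ZT hours, so
ZT12--24 includes the lights-off boundary bin starting at ZT12 and nothing
is counted twice.

The four temperature-response indices share one template. For each fly,
take the mean of its binned activity (or sleep minutes) over a fixed ZT
window under two temperature conditions, form a relative difference, then
average over flies (days within a condition are averaged first, so the fly
is the statistical unit):

* evening-peak advance (cooling): (ZT6--12 activity at 18 °C − at 24 °C) / at 24 °C;
* evening-peak offset delay (heating): (ZT12--18 activity at 30 °C − at 22 °C) / at 22 °C;
* night-time sleep reduction (heating): (ZT12--24 sleep at 22 °C − at 30 °C) / at 22 °C;
* evening sleep reduction, cold variant: (ZT6--12 sleep at 18 °C − at 24 °C) / at 24 °C,
  and hot variant: (ZT12--18 sleep at 30 °C − at 22 °C) / at 22 °C.

Signs are implemented exactly as published; note the cold evening-sleep
variant is positive when cooling *increases* evening sleep, which the
result metadata flags. A fly whose denominator-window mean is zero has no
defined index and is excluded with a warning. Because each fly contributes
a ratio, the group mean carries a small positive finite-sample bias
relative to the ratio of population means (roughly the effect size times
the squared coefficient of variation of the denominator window); recovery
comparisons against the oracle expectation sit within sampling error but
systematically on the high side, which is a property of the index itself,
not of the implementation.

A caution about permutation "nulls" for ratio indices: when a genuine
effect is present, swapping the two condition labels within each fly does
*not* drive the group mean to zero, because `(A-B)/B` and `(B-A)/A` do not
cancel (their average is `(r + 1/r)/2 - 1 > 0` for a true ratio `r`). The
package's null sanity suite therefore permutes labels on *exchangeable*
cohorts — both labels generated with identical parameters — where the
indices genuinely sit at zero within sampling error; on a planted-effect
cohort the permuted mean is only checked to collapse far below the effect.

Group comparisons use one-way ANOVA with Tukey's HSD post test (a
two-tailed t test for two groups) and a compact letter display computed by
insert-and-absorb directly from the pairwise p-value matrix, so two groups
share a letter exactly when their comparison is non-significant at
alpha = 0.05. When every group is internally constant there is no error
term; the test is skipped with a message and letters fall back to exact
equality of means.

## Calcium traces: dF/F0, step responses, saturation, gating

Fluorescence change is `dF/F0 = (F_t - F0)/F0 x 100%` and its windowed
maximum `dFmax/F0`. The strict reading of F0 — the fluorescence at time
zero — is a single sample and fragile under shot noise, so the default F0
is the mean over a pre-stimulus baseline window, with `f0_method =
"literal"` reproducing the single-sample definition. dF/F0 is exactly
invariant to multiplying a trace by a positive constant; it is *not*
invariant to additive offsets (background subtraction matters), and the
test suite asserts both.

Temperature stimuli are baseline-plus-ramped-steps; the rig model reaches a
commanded step linearly in about 80 s (the default ramp). A step's response
is quantified from window means of the fluorescence — ratiometric
(GCaMP/tdTomato) whenever a partner trace is available — before the onset
and after the ramp completes: the relative fold change is post/pre, and an
ROI is classified activated/inhibited when the change exceeds k = 2
pre-window SDs (k configurable; the paper-scale choice of window lengths is
likewise exposed because the original lengths are not stated). For
inhibition the signed extremum of dF/F0 (largest magnitude, sign kept) is
reported alongside the plain maximum, and outputs always state which is
which.

The synthetic step response is `R(dT) = sign(dT) min(|dT|/dT_sat, 1)`,
saturating 6 °C below baseline for cooling and 8 °C above for heating, low-
pass filtered with a 15-s sensor time constant (exact first-order update).
`saturationSummary()` groups responses by step amplitude per sign, flags
adjacent amplitudes whose means differ by less than 5% of the dynamic range
and estimates the saturation amplitude as the smallest |dT| from which all
larger amplitudes stay within tolerance of the plateau; a Spearman rank
test reports the monotone trend. With 2-°C amplitude spacing, recovery
within one grid step is the validated accuracy.

Circadian gating of the step response is estimated from responses grouped
into recording windows (ZT0--2, ZT6--8, ZT10--14, ZT17--19 by default).
The gain per window is the mean |post − pre| on the ratiometric scale —
chosen over fold change or dF/F0 because the ratiometric difference is
proportional to the evoked drive alone and independent of the diurnal
baseline, so a planted night:day gain ratio is recovered without
baseline-induced bias. Percentile bootstrap CIs (1000 resamples, seeded)
accompany each gain, and ratios are reported against the weak daytime
reference window ZT6--8.

Correlation/clustering uses Pearson r on traces linearly interpolated onto
a common grid at the coarsest native rate (no extrapolation), hierarchical
clustering with average linkage on 1 − r, and a deterministic leaf order;
zero-variance traces are reported as missing and excluded with a warning.
Per-trace z-scored matrices are exported for heat maps in both raw and
z-scored form, since published heat-map normalizations often go unstated.

## The 24-h diurnal curve from phase-shifted groups

Long-term imaging of one fly across 24 h is impractical, so the diurnal
curve is assembled from four groups entrained with light-schedule shifts of
0, 6, 12 and 18 h, each fly imaged every 30 min over 6 h of its local time
(13 samples) in both channels. Each sample maps to ZT = (local time +
shift) mod 24; the GCaMP/tdTomato ratio cancels any common multiplicative
drift exactly (bleaching, laser power), which the tests assert at 1e-9
relative. Samples pool into half-open 30-min bins labeled by center, with
the ZT23.5--24 bin closing the circle; flies are the unit (within-fly means
per bin first, then mean ± SEM over flies, pooling flies across groups at
window-edge overlaps rather than averaging group averages). Whether the
original analysis normalized per fly before averaging is not stated;
per-fly-first is the default here because it makes the SEM a between-fly
quantity matching the reported n. Empty bins stay missing — no
interpolation. `doublePlot()` repeats the curve with a +24 h offset for
display and `undouble()` inverts it exactly.

Because samples sit on the same 30-min grid as the bins, each bin holds
samples taken at its left edge; noiseless recovery is therefore exact at
the sampled times, and the noisy-recovery test compares against the
planted baseline evaluated there. The noisy tolerance is derived from the
sampling distribution of the RMSE: with per-sample noise SD sigma and n = 6
flies per bin, RMSE² = sigma²/(6·48) · chi-square(48), and the bound is
taken at the 99.9% quantile — the *expected* RMSE itself (sigma/sqrt 6)
would be exceeded half the time and is not a usable test bound.

## Connectome partner ranking

Connection tables follow the neuPrint export dialect (`bodyId_pre,
type_pre, bodyId_post, type_post, weight`). Loading sums duplicate body
pairs and labels missing types "untyped". Ranking is type-level (matching
the published type-grouped Sankey), sums weights over all connections whose
pre (downstream) or post (upstream) type equals the source, drops partners
under `min_weight` (default 1 — the threshold used for the published
figures is unstated, so the value is echoed in output metadata), and breaks
weight ties lexicographically for determinism. Retained plus dropped weight
equals the total source-incident weight, and downstream/upstream rankings
are dual; both are asserted against brute-force nested-loop sums. The
Sankey export is a plain nodes/links JSON consumable by standard renderers.

## The synthetic generator

The generator is first-class, tested code; its defaults are the emulated
study conditions and are not tuned per analysis.

Wake and sleep come from a two-state Markov chain at 10-s epochs with
transition probabilities `P(wake to sleep) = r(1 - w(zt))` and `P(sleep to
wake) = r w(zt)`, so the stationary wake probability at frozen ZT is
exactly the diurnal profile w(zt) (alert after lights-on, midday siesta,
evening alertness, consolidated night sleep) while `r = 0.05` sets
realistic bout scales (minutes to tens of minutes). Movement counts are
Poisson at a diurnal rate — baseline 0.1 counts/epoch plus circular-
Gaussian morning (ZT1) and evening (ZT11) peaks — while awake, and
structurally zero while asleep. Temperature conditions modify the rate
(cold 1.30x with a 1-h evening-peak advance and raised siesta-window
wakefulness; hot 1.50x with a 1-h delay and +0.30 night wakefulness),
chosen once to match the direction and rough size of the reported
behavioral effects.

`expectedWindowMean()` is the oracle the index tests compare against: it
integrates rate x P(wake) deterministically, with P(wake) from forward
iteration of the chain's marginal — an independent route from sampling.
Scored sleep has no closed form (bout structure and Poisson zeros during
quiet wakefulness both matter), so `expectedSleepWindowMean()` reports a
large-cohort simulation estimate and labels its method accordingly.

Calcium traces follow latent activity `a(t) = b(zt) + s g(zt) R(dT(t))`
with the diurnal baseline b peaking near ZT10, gating g equal to 4 in
ZT10--14 and ZT17--19 and 1 elsewhere (the planted 4:1 night:day ratio),
and per-class gains. LNd and DN3 receive inhibitory coupling from DN1a's
stimulus-evoked drive `s g R` (weights −0.6 and −0.8); the coupling
deliberately excludes DN1a's own baseline b so that ablating DN1a (which
reduces coupling to a configurable residual, default 0) removes the evoked
response without shifting resting fluorescence. The latent signal is low-
pass filtered (single-pole, exact exponential update) and rendered as
GCaMP = F0(1 + kappa a) x bleach + noise against a tdTomato channel
carrying only bleach and noise. Per-fly and per-trace seed substreams are
derived from the master seed by counter, so enlarging a cohort never
reshuffles existing members and identical configurations are bit-identical.

What the synthetic validation does not show: the generator has no motion
artifacts, no ROI segmentation error, no correlated (non-white) noise, no
adaptation or habituation of the temperature response, and its wake/sleep
process is memoryless within state. Passing recovery tests demonstrates the
estimators are unbiased and correctly implemented under the stated model,
not that the model captures every property of live-fly recordings.

## Problem sizes and numerics

The validation suite uses cohorts of 64 flies for index recovery, 8--12
traces per condition for calcium recovery, 6 flies per diurnal group, 100
seeded repetitions for the gating and clustering recovery rates and 200
random layouts for the letter-display consistency check — sizes chosen to
match the study's per-figure n while keeping each recovery experiment's
Monte-Carlo error well below its acceptance band. Ties in the evening-peak
search resolve to the earlier bin; SEM over fewer than two values is
reported missing, never zero; all file outputs are delimited text or JSON
with full-precision floats, and run manifests contain no timestamps so
identical seeds reproduce byte-identical artifacts.
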