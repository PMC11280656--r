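---
title: "Detecting engagement onsets in electrodermal activity with moving-average crossovers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting engagement onsets in electrodermal activity with moving-average crossovers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 7, fig.height = 4)
library(edacross)
```

## The signal and the problem

Electrodermal activity (EDA, also called galvanic skin response) is skin
conductance in microsiemens, driven by sudomotor sympathetic activity. It
decomposes into a slow *tonic* level (SCL) that drifts over minutes and fast
*phasic* skin conductance responses (SCRs) — transient peaks a few seconds
wide that follow arousing events with a physiological latency of roughly
1–5 s. In media-viewing and learning settings, a sustained falling tonic
trend indicates disengagement and a rising trend (especially with frequent
SCRs) indicates engagement; isolated SCR peaks mark momentary arousal that
need not amount to sustained engagement.

`edacross` answers a practical question about such recordings: *when* does a
viewer's engagement state change? Classical session summaries (mean EDA,
trend slope, peak counts) describe a whole session but are poor change
detectors. The package's core is a trend-reversal detector borrowed from
financial chart analysis: two simple moving averages (SMAs) of the same
signal with different time windows. The short window tracks recent level,
the long window tracks history; when the short-window SMA crosses **above**
the long-window SMA we call it an **engagement crossover** (the "golden
crossover" analogue), and the reverse crossing a **disengagement crossover**.

## The crossover detector

Both SMAs are *trailing* (causal): the value at time $t$ averages
$[t - W, t]$. This is a deliberate choice — a causal detector can run in
real time, e.g. inside an intelligent tutoring system, and it produces the
characteristic detection lag of a few tens of seconds after a trend change
rather than an acausal early flag. During warm-up (before a window has
filled) the mean over the available samples is used; events that fall before
the long window has filled are flagged and excluded from the engagement
timeline by default, because both averages are still transients of the
recording start.

Defaults are $W_s = 30$ s and $W_l = 180$ s. Window sizes are genuinely
unoptimized free parameters of the method; both are exposed in
`crossover_config()`.

Two structural properties are worth stating precisely, because the test
suite asserts them exactly rather than approximately:

* **Baseline/affine invariance.** Both SMAs are linear in the signal, so
  under $y \mapsto a\,y + b$ with $a > 0$ the difference
  $\mathrm{SMA}_s - \mathrm{SMA}_l$ scales by $a$ and its sign pattern — and
  therefore every crossover time — is unchanged. Baseline correction and
  min–max normalization move only the ordinate. The detector needs no
  baseline measurement at all.
* **An analytic detection lag.** For an idealized V-shaped reversal (tonic
  slope $-m$ switching to $+m$ at $t^\ast$), integrating the trailing
  averages across the kink gives a crossing at $t^\ast + x$ where $x$
  solves a quadratic in the two windows; for $W_s=30, W_l=180$ it is
  $x^2 - 360x + 18900 = 0$, whose admissible root is $x \approx 63.8$ s.
  The discrete 128 Hz detector reproduces this to within a second, and the
  magnitude is consistent with the ~30–65 s prediction lags one observes on
  real profiles. Note the lag is independent of $m$: steeper reversals are
  not detected faster, only more robustly.

### Event triage

Raw sign changes include crossings that no analyst would call a state
change. Each event is therefore triaged by how long the SMA difference keeps
its new sign:

* `false_positive` — the sign reverts within `fp_reversal` seconds
  (default 10 s, "within a few seconds");
* `discounted` — the direction holds but for less than `sustain_min`
  seconds (default 60 s, "correct yet short-lived");
* `sustained` — everything else; only these drive the engagement timeline.

The two horizons operationalize verbal categories, so they are configuration,
not constants; the defaults separate SCR-driven excursions (tens of seconds,
set by the ~30 s short window and the few-second SCR width) from genuine
trend changes (minutes).

The `engagement_timeline()` bookkeeping starts the stimulus in a `warmup`
state until the first sustained event or until the long window has filled,
inheriting the SMA-difference sign at that point, and then switches state
only at sustained events.

## Session metrics

On the cleaned, normalized signal the package computes the classical
summaries: baseline-corrected mean EDA (stimulus mean minus the mean of the
60 s gray-screen baseline) and the OLS trend slope over the stimulus. Both
are computed on the normalized signal, which makes per-type mean-EDA values
like $-0.42$ (a profile that decays from near the top to near the bottom of
its own range) directly interpretable; whether one fits the slope on raw or
normalized values is not fixed by convention, and we chose normalized —
the two differ only by the positive factor $1/(\max - \min)$, so signs and
correlations are unaffected. `eda_pearson()` reports $r$, $df = n-2$ and the
two-tailed $p$ from $t = r\sqrt{df/(1-r^2)}$; at $df = 19$, $r = 0.416$
maps to $p \approx 0.061$.

## Latency estimation

The response latency is the delay between stimulus onset and the first
discernible rise of the signal. The operational rule:

1. compute the trailing 1 s local OLS slope of the (unsmoothed) trace;
2. calibrate a threshold from the baseline segment: mean $+ k \cdot$ SD of
   its local slopes ($k = 3$ by default);
3. trigger at the first time within `search` = 10 s of onset where the
   slope exceeds the threshold and holds for `hold` = 0.5 s;
4. refine: backtrack to where the slope last sat at its baseline mean, then
   fit a local flat-then-rising two-piece model around that point and take
   the changepoint (reported as the last flat sample).

Step 4 matters. A pure threshold crossing fires systematically *after* the
true onset (the slope must accumulate above noise), a bias of a few tens of
milliseconds that the changepoint fit removes; onset refinement of this kind
is standard in SCR scoring. The estimator runs on the unsmoothed trace
because the centered 1 s cleaning average would smear the onset half a
window backwards. It never returns negative values, returns `NA` when
nothing rises in the search window, and is weakly monotone in $k$ (a
stricter threshold can only delay or lose the trigger). On clean injected
onsets it recovers the true latency to ~0.02 s at 128 Hz.

## Morphology classification

Five recurring profile shapes are used to describe whole sessions:

| Type | Shape | Reading |
|------|-------|---------|
| I    | long smooth decrease | sustained disengagement |
| II   | decrease, sporadic peaks | disengagement with isolated arousal |
| III  | decrease, multiple peaks | momentary engagement, falling overall |
| IV   | increase, multiple peaks | sustained engagement |
| V    | decline then rise (or reverse) | a state switch |

Human raters classify these visually; `classify_morphology()` is a
reproducible surrogate built from three features of the normalized stimulus
segment: the OLS trend slope, the detected peak rate, and a single-breakpoint
two-segment fit. Type V is claimed only when the two-segment fit reduces the
SSE by at least 25% *and* the segment slopes have opposite signs — the
second condition is what keeps peaky but monotone profiles (Types III/IV)
from masquerading as reversals. Otherwise the slope sign picks rising
(Type IV) vs falling, and the peak rate splits I/II/III.

Peaks are local maxima with a topographic prominence of at least 0.05
normalized units and at least 5 s separation, computed on the local-extrema
envelope so sub-threshold noise ripple costs nothing. The rate thresholds
are conventions for inherently verbal categories: `r_sporadic` = 0.15
peaks/min (a single detected peak in a 5–10 min video already counts as
"sporadic" rather than "none") and `r_multiple` = 1 peak/min. The
sporadic/multiple boundary in particular has no quantitative definition in
the literature; both knobs are exposed in `morphology_config()`.

## The synthetic-data generator

Every quantitative claim the package tests is validated against simulated
sessions with known ground truth, because the annotated human recordings
this methodology was developed on are published only as figures. The
generator (`generate_profile()`, `generate_session()`) emulates the study
design:

* **protocol** — 30 s instruction screen, 60 s flat-tonic gray-screen
  baseline, a stimulus of 333/595/291 s (the three study videos, for
  `generate_session()`), 6 s end slide; 128 Hz sampling;
* **tonic** — continuous piecewise-linear SCL, default start level 8 µS and
  drift magnitude 0.003 µS/s during the stimulus (≈ 0.2 µS/min, a typical
  slow drift), falling on disengaged truth intervals and rising on engaged
  ones; Type V switches slope sign once, by default at the stimulus
  midpoint;
* **phasic** — SCRs as a unit-peak bi-exponential kernel
  $e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r = 0.75$ s, $\tau_d = 2$ s
  (the canonical sudomotor shape; analytic argmax
  $\ln(\tau_d/\tau_r)\tau_r\tau_d/(\tau_d-\tau_r) \approx 1.18$ s),
  amplitudes drawn from 0.2–0.6 µS. Densities follow the verbal type
  definitions: 0/min (Type I), 0.3/min (Type II, ~2 peaks per video),
  1.5/min (Types III/IV); counts are deterministic for a given rate and
  duration so that a "sporadic" session cannot, by sampling accident,
  contain no peaks at all;
* **noise** — additive white Gaussian, default SD 0.01 µS, i.e. sub-second
  wiggle that the 1 s cleaning average suppresses.

Amplitudes, drift rates and noise levels are conventions chosen to be
physiologically plausible — the source material shows only qualitative
peaks — and are all arguments, not constants. Sessions are seed-deterministic
(identical arguments and seed give bitwise-identical traces) and the
generator restores the caller's RNG state.

What the simulator deliberately does *not* model: motion artifacts,
electrode drift and detachment, sweat-gland biophysics, SCR shape
variability between individuals, or superposed/overlapping SCRs. Passing
the simulation batteries therefore shows the algorithms are correct on
signals with the assumed tonic/phasic structure; it does not certify
performance on artifact-laden field recordings.

## Validation batteries and problem sizes

The package's own end-to-end checks (the `acceptance` test file and
`scripts/acceptance.R`) use these study-scale batteries:

* affine invariance of crossover times on 50 mixed-morphology sessions,
  asserted exactly (shift must be 0);
* the analytic 63.8 s V-reversal lag at 128 Hz, within 1 s;
* switch recovery on 200 Type V sessions with the switch drawn uniformly in
  the middle of the stimulus (45–65% of its length, so that the crossover
  and its 60 s sustain window fit before the video ends), tonic slope
  0.004 µS/s against noise SD 0.001 µS — a trend at least four times the
  noise, per the battery's design condition. At least 95% of switches must
  be matched by a sustained engagement event within $(W_s+W_l)/2 = 105$ s,
  with under one false sustained event per session on average;
* morphology recovery on 100 sessions (20 per type, default generator and
  classifier settings), at least 90% correct;
* latency recovery on 21 sessions (7 participants × 3 videos) with true
  onsets drawn uniform(1, 5) s: mean absolute error at most 0.5 s and all
  estimates inside the physiological 1–5 s band;
* the analytic $r = 0.416,\ df = 19 \Rightarrow p \approx 0.061$ mapping,
  checked on data constructed to have exactly that correlation.

## Numerical choices and degenerate inputs

* Windows are converted to sample counts by `round(window * fs)`; the
  cleaning average is centered with shrinking edge windows (no phase
  shift), the crossover averages are trailing (causal).
* Exact SMA ties produce no event until a strict sign change.
* Min–max normalization refuses constant recordings rather than emitting
  NaNs; readers reject non-monotone time axes and gaps longer than two
  sample periods rather than repairing them.
* Segments are half-open `[start, end)`, times are seconds from recording
  start; at 128 Hz a 60 s baseline is exactly 7680 samples.
* The breakpoint search uses a ~2 s candidate grid with 30 s edge margins
  and prefix-sum OLS, so its cost is independent of sampling rate for
  fixed duration.

## Known limitations

* Crossover window sizes are demonstrative defaults; no claim of
  optimality is made, and exponential/weighted averages are not
  implemented.
* The morphology thresholds operationalize verbal categories; on real data
  near-boundary profiles (II vs III especially) will be sensitive to them.
* The latency estimator assumes an identifiable flat-to-rise transition at
  stimulus onset; gradual or absent onsets return `NA` by design.
* Detection lag is inherent to trailing averages (~64 s for symmetric
  reversals at the default windows); applications needing faster reaction
  must shorten the windows and accept more false crossings.

## A worked session

```{r example}
s <- generate_session(1, "TypeV", seed = 42)
fit <- eda_engagement(s$trace, s$protocol)
summary(fit)
plot(fit)
```

The timeline above switches from disengaged to engaged roughly a minute
after the true tonic reversal at `r round(s$truth_states$start[2], 1)` s —
the expected causal detection lag — and the session is labelled Type V with
a negative-then-positive segment-slope pair.
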