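# edacross

Engagement analysis of electrodermal activity (EDA) recordings via
dual-window moving-average crossovers.

## What problem this solves

EDA (galvanic skin response) — skin conductance in microsiemens — rises
with sympathetic arousal. In media-viewing and learning studies, the slow
*tonic* trend of the signal tracks sustained engagement (rising) or
disengagement (falling), while fast *phasic* skin conductance responses
(SCRs) mark momentary arousal. Session summaries like mean EDA and trend
slope describe a whole recording but say nothing about **when** a viewer's
state changed.

`edacross` implements a change detector for this problem: two trailing
simple moving averages (SMAs) of the same signal, a short window
(W<sub>s</sub> = 30 s) and a long one (W<sub>l</sub> = 180 s). When the
short average crosses **above** the long average we have an *engagement
crossover* — the analogue of the golden crossover of financial chart
analysis; the reverse crossing is a *disengagement crossover*. Each event
is triaged by how long the SMA difference keeps its new sign: sign reversal
within 10 s ⇒ `false_positive`; correct direction but shorter-lived than
60 s ⇒ `discounted`; otherwise `sustained`. Only sustained events switch
the session's engaged/disengaged timeline.

Because both averages come from the same signal, crossover **times** are
exactly invariant under any positive affine rescaling y → a·y + b: the
method needs no baseline measurement. For an idealized V-shaped reversal
with the default windows, the detection lag is the root of
x² − 360x + 18900 = 0, i.e. ≈ 63.8 s — a property the test suite checks
against the discrete 128 Hz implementation.

Around the detector the package provides the full analysis chain for
128 Hz single-channel recordings with a 60 s gray-screen baseline:

- **preprocessing** — 1 s centered moving-average cleaning, min–max
  normalization `(x − min)/(max − min)` per recording;
- **session metrics** — baseline-corrected mean EDA, OLS trend slope,
  Pearson correlation with self-report engagement scores (r, df = n−2,
  two-tailed t-based p);
- **latency** — stimulus-response latency from a baseline-calibrated
  slope threshold with changepoint onset refinement (physiological band
  1–5 s);
- **morphology** — classification of a stimulus profile into five types:
  I smooth decrease, II decrease with sporadic peaks, III decrease with
  multiple peaks, IV increase with multiple peaks, V declining-then-rising
  reversal; built from trend slope, prominence-based peak rate, and a
  single-breakpoint two-segment fit;
- **a synthetic-EDA simulator** — piecewise-linear tonic level,
  bi-exponential SCR kernel (rise 0.75 s / decay 2 s), Gaussian noise,
  seed-deterministic, with ground-truth engagement states and SCR times —
  so every stage is testable end to end without human data;
- **file formats** — `time_s,eda_us` CSV traces, YAML protocols, CSV event
  tables, JSON truth/reports, plus a thin CLI at `inst/cli/edacross`
  (`simulate`, `analyze`, `crossover`, `classify`, `latency`).

## Worked example

```r
library(edacross)

s   <- generate_session(1, "TypeV", seed = 42)  # video 1: 333 s stimulus
fit <- eda_engagement(s$trace, s$protocol)
summary(fit)
```

```
<eda_engagement> TypeV profile; mean EDA (baseline-corrected) -0.262; slope 8.01e-05 /s
  latency: none detected; crossovers: 11 (1 sustained after warm-up)
<eda_protocol> baseline [30, 90) s, stimulus [90, 423) s  (participant NA, video 1)
  normalization: min 7.501, max 8.418 uS
  crossover triage:
               triage
direction       discounted false_positive sustained
  disengagement          1              3         1
  engagement             2              3         1
  engagement timeline:
    start      end      state
  90.0000 180.0000     warmup
 180.0000 321.9453 disengaged
 321.9453 423.0000    engaged
```

Reading this: the simulated session is a Type V profile whose tonic trend
reverses (disengaged → engaged) at 256.5 s; the detector reports the
sustained engagement crossover at 321.9 s — the expected ~65 s causal
detection lag — while the ten other crossings (SCR- and noise-driven) are
triaged away as false positives or discounted. The baseline-corrected mean
EDA of −0.262 says the stimulus ran about a quarter of the signal's range
below baseline on average; no response latency is reported because this
profile starts falling at the stimulus onset instead of rising.
`coef(fit)`, `predict(fit, times)` and `plot(fit)` give the metric vector,
the state at arbitrary times, and the annotated profile plot.

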