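---
title: "Whole-brain calcium imaging: baseline, events, seizures and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain calcium imaging: baseline, events, seizures and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrace)
library(dplyr)
```

## The analysis problem

Wide-field epifluorescence imaging of GCaMP-expressing larval zebrafish
yields one slowly drifting, noisy fluorescence trace per animal — the mean
intensity of a whole-brain region of interest sampled at 1.33 Hz for an
hour. The scientific questions asked of such recordings are about
*excitability*: how often does the brain produce calcium transients, how
large and long are they, how much total activity accumulates (area under
the ΔF/F₀ curve), does the animal have epileptic seizures, and how do
these quantities differ between genotypes or drug conditions (galanin
overexpression, galanin or galanin-receptor loss, PTZ exposure, the
*eaat2a⁻/⁻* seizure model). `calcitrace` implements that workflow as
data-frame-in / tibble-out verbs so whole cohorts can be analysed with
ordinary dplyr pipelines.

## Model and procedure

**Baseline and ΔF/F₀.** Raw fluorescence mixes the signal of interest
with slow drift (focus, bleaching, dye distribution). The baseline F₀ at
frame *k* is defined as a low percentile — by default the 1st — of the
raw values inside a moving window centred on *k* (150 s for normal
activity, 300 s for seizure-model recordings whose events last minutes;
a longer window prevents the baseline from climbing into the seizures
themselves). The fractional change is then

ΔF/F₀(k) = 100 · (F(k) − F₀(k)) / F₀(k)  [percent].

Percentiles use the linear-interpolation (type 7) definition, the window
is truncated — not padded — at the recording edges, and a trailing-window
mode is available because the original description does not fix the
placement. The window percentile is computed in compiled code
(`src/roll_quantile.cpp`); a pure-R sort-and-interpolate oracle in the
test suite checks it frame by frame on random traces.

We read "baseline as 1% of the total fluorescence within a moving
window" as the 1st percentile of the windowed values: a 0.01 × sum
reading would not produce a quantity on the scale of F at all, whereas
the sliding low percentile is the standard quiescent-level estimator for
this kind of data.

**Events.** A Ca²⁺ event is a maximal run of frames with ΔF/F₀ strictly
above a threshold; onset is the first supra-threshold frame, offset one
sampling interval after the last (half-open intervals throughout). Two
tiers are analysed, "above 5%" and "above 10%", by re-running detection
per tier, so tier counts are nested by construction; an exclusive-band
mode ([5, 10), [10, ∞)) exists for sensitivity analyses. No hysteresis,
minimum duration or refractory period is imposed — none is part of the
published rule. For hypoactivity analyses of seizure-model larvae an
exclusion filter removes events that are both large and long
(amplitude > 50% **and** duration > 20 s); the conjunction is the
published rule, an OR variant is selectable.

**Seizures.** A seizure is an excursion whose peak reaches **at least**
100% ΔF/F₀, bounded by its 50% crossings: onset at the first frame above
50%, offset at the first frame back below. A run still above 50% when
the recording ends is kept, flagged `truncated`, counted toward seizure
numbers, and dropped from duration statistics by default (multi-minute
tapering seizures make this case real). For the averaged waveforms every
seizure is aligned at the first frame reaching 50% of its own maximum;
segments are placed on a common grid, padded with `NA` outside the
recording, and averaged per timepoint with the SEM. Per-seizure AUC
(trapezoid, missing padding contributing zero) and time to peak are
measured from the start of the aligned segment.

**Group statistics.** Continuous measures (amplitude, duration, AUC,
time to peak) are compared with the two-sided Wilcoxon–Mann–Whitney
test: exact enumeration when both samples are tie-free and the smaller
has ≤ 8 observations, otherwise the normal approximation with mid-ranks,
tie and continuity corrections. Event and seizure counts are
overdispersed, so they are compared with a log-link negative-binomial
GLM (`MASS::glm.nb`, dispersion profiled by maximum likelihood); the
effect is the rate ratio `exp(β)` with a Wald p-value (likelihood-ratio
optional). A Shapiro–Wilk report per group is provided as in the
original protocol, but it is a report, not a branch — the nonparametric
tests are used regardless. No multiple-testing correction is applied,
matching the source analysis; users comparing many measures should
correct downstream. Significance labels follow the conventional
thresholds (*** < 0.001, ** < 0.01, * < 0.05, ns otherwise).

**qPCR.** Primer efficiency is the dilution-series slope transform
`10^(−1/slope) − 1` (acceptable within [0.9, 1.1]). Relative expression
uses the ΔΔCt method against a three-gene reference panel (*actb1*,
*tbp*, *rpl13a*): technical replicates are averaged per sample × gene,
each sample's reference Ct is the arithmetic mean of its reference-gene
Cts — algebraically the geometric mean of their expression levels, which
is why permuting the reference genes changes nothing — ΔCt is target
minus reference, ΔΔCt the case-minus-control difference of mean ΔCt, and
the fold change 2^(−ΔΔCt). Base-2 amplification is assumed after the
efficiency-equality check, as in the source workflow; a Pfaffl-style
efficiency-corrected mode is available but off by default.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `baseline_window_s` | 150 (300 for seizure models) | s | window of the percentile baseline |
| `baseline_percentile` | 1 | % | quiescent-level percentile |
| `event_thresholds_pct` | 5, 10 | % ΔF/F₀ | published event tiers |
| `exclusion_amp_pct` / `exclusion_dur_s` | 50 / 20 | % / s | hypoactivity seizure-exclusion filter |
| `seizure_peak_threshold_pct` | 100 | % ΔF/F₀ | seizure definition (inclusive) |
| `seizure_boundary_threshold_pct` | 50 | % ΔF/F₀ | onset/offset crossings |
| `align_fraction` | 0.5 | — | alignment at 50% of each seizure's maximum |
| `align_pre_s` / `align_post_s` | 0 / 400 | s | aligned-segment extent; 400 s accommodates >6 min seizures |

## The synthetic-cohort generator

Raw recordings are not redistributed with the package, so every stage is
exercised on synthetic cohorts with known ground truth:

F(t) = B · (1 + drift(t)) · (1 + Σ kernels(t)/100) + ε(t),

with B the quiescent level, a slow sinusoidal multiplicative drift
(default 5% amplitude, 30 min period), additive Gaussian noise (default
SD 1% of B), and transient kernels that rise linearly and decay
exponentially — a minimal GCaMP-like shape whose threshold crossings
have closed forms, so the generator can hand the test suite exact
expected onsets and durations (`truth_crossings()`). Small events default
to 5–10% amplitude at 2/min, large events to 10–50% at 1/min, seizures
to ≥100% with a 20 s rise and either an abrupt (tens of seconds) or
tapering (minutes) exponential decline, emulating the contrast between
control-like and galanin-deficient seizure offsets. Multiplicative
composition keeps a kernel's ΔF/F₀ amplitude equal to its configured
value regardless of drift. Default group-effect multipliers encode the
directions of the galanin perturbations (overexpression halves the
large-event rate; loss doubles the small-event rate and shrinks
amplitudes). Event and seizure rates, amplitude ranges and kernel time
constants are testing conventions — the study's true event statistics
are not published — and the defaults were fixed once, up front, at
values a calcium-imaging practitioner would call realistic.

Three generator properties are deliberate idealisations: kernels are
truncated to exactly zero once their contribution falls below 0.1%
ΔF/F₀, kernel supports are placed without overlap (a few frames of
padding), and seizures stay clear of the recording edges unless a test
asks otherwise. Together these guarantee that noiseless traces contain
exactly-quiescent frames in every baseline window and that each seeded
kernel produces exactly one detection run, which is what makes the
100%-precision/recall recovery checks meaningful. Real recordings have
none of these guarantees — overlapping events, airy noise floors,
movement artefacts — so passing recovery tests demonstrates correctness
of the detectors' logic, not field performance on noisy data.

## Numerical and design choices

- **Strict inequality** (`dff > threshold`) defines supra-threshold
  frames, matching "above 5%"; the seizure peak rule "at least 100%" is
  inclusive (`>=`).
- **Trapezoidal integration** for all AUCs: exact for the piecewise
  linear traces the generator emits, standard otherwise.
- **Truncated seizures**: counted as seizures, excluded from duration
  comparisons; their offset is the trace end.
- **Events at recording edges** are counted and flagged `truncated`
  (the published rule is silent; discarding them would bias counts low).
- **Exact vs approximate rank-sum**: enumeration is used only for
  tie-free samples with min(n) ≤ 8; beyond that the normal approximation
  is standard and accurate.
- **Poisson boundary**: when the negative-binomial dispersion estimate
  diverges (under-dispersed counts, e.g. every larva having exactly one
  seizure), the fit falls back to the Poisson limit (θ → ∞), is flagged
  `unstable`, and still reports the rate ratio.
- **Zero-variance groups** in the Shapiro–Wilk report are returned as
  `degenerate` rather than an error mid-pipeline.
- **Manifest determinism**: run manifests record the config snapshot,
  seed, group sizes and per-stage record counts, but no wall-clock
  timings — reports are required to be byte-identical across reruns of
  the same inputs, and timings would break that by construction.
- **Interface**: the pipeline is a set of composable functions plus two
  orchestrators (`run_activity_analysis()`, `run_seizure_analysis()`)
  and report writers; analyses in this field are driven from scripts and
  notebooks, so no shell executable is shipped.

## Problem sizes used in the shipped checks

The test suite and the acceptance script scale the study design down to
keep full runs fast while preserving every contrast of interest:
recordings of 300–1200 s instead of 1 h (seizing status and recovery
accuracy do not depend on trace length), cohorts of 8–39 larvae
(the seizing-fraction cohorts use the study's exact denominators: 21,
35, 39 and 38 animals), 200 baseline-oracle traces, 200 + 500
negative-binomial replicates, and 100-seed qPCR noise sweeps. These
sizes are the package's own choices and are stated here so that anyone
re-running the checks knows what was actually computed.

## Known limitations

- The pipeline analyses one whole-brain ROI per larva (with an option to
  average several ROI columns); it does not segment ROIs or analyse
  per-region propagation.
- The qPCR module computes fold changes and their per-sample spread; it
  does not test fold changes inferentially (the source analysis did that
  in external software), nor does it model melting curves or
  contamination controls.
- The ΔΔCt method assumes near-equal primer efficiencies; use the
  efficiency-corrected mode when the dilution series says otherwise.
- Detection has no denoising stage; at very low SNR the strict
  threshold-crossing rule will fragment events. The published protocol
  has the same property.
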