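---
title: "Methods: sensor-diary agreement for physical-activity assessment"
author: "actidiary developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-diary agreement for physical-activity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actidiary)
```

## The problem

Wearable accelerometers summarize bodily movement as ENMO — the Euclidean
norm of the tri-axial acceleration minus 1 g, negatives truncated to zero —
while activity diaries summarize the same day as energy expenditure in METs
(multiples of resting metabolic rate, assigned from a Compendium-style
catalogue via the wearer's self-reported intensity). The two measures live
in different units and magnitudes, but over a common grid of 15-minute
daytime epochs their temporal profiles should agree if the sensor placement
captures whole-body activity well. `actidiary` quantifies that agreement for
three sensor positions (ankle, wrist, lower back): both arms are Min-Max
normalized, a one-parameter linear calibration `MET = alpha * ENMO` is
fitted on group-mean profiles by Nelder-Mead, and per-participant RMSE
distributions of the alpha-corrected sensor signal against the diary
reference are summarized and stratified by tremor severity. This matters
particularly in Parkinson's disease, where tremor can inflate wrist-worn
ENMO without any corresponding energy expenditure.

## Signal chain and its conventions

**ENMO.** Per sample, `sqrt(ax^2 + ay^2 + az^2) - 1`, then a zero-phase
(forward-backward) 4th-order Butterworth low-pass at 20 Hz, then truncation
of negatives to zero. The sentence order of the standard pipeline
description implies filtering the norm-minus-one signal *before*
truncation; that literal order is the default (`mode = "post_norm"`), and a
per-axis pre-filtering variant common in the field is available
(`mode = "per_axis"`), plus a `bypass` mode that makes the operation an
exact norm-minus-one-truncate map (used as its own test oracle). Zero-phase
filtering is chosen so outputs stay aligned with input timestamps; phase
handling is otherwise unspecified in the source protocols. The filter
design and `filtfilt` (odd-reflection padding, steady-state initial
conditions) were implemented in R because no suitable package is available
in the target environment; both are verified against frozen outputs of
scipy.signal 1.17.1 at machine precision.

**Epochs and slots.** 5-second epochs are anchored on the wall clock with
half-open intervals `[start, start + 5 s)`; empty epochs are omitted, never
zero-filled (zero-filling would bias ENMO downward). The daytime window
09:00–18:00 comprises 36 half-open 15-minute slots — "nine hours" and the
15-minute grid are only mutually consistent with half-open slots. A slot's
value is the unweighted mean of its present 5-second epochs; a slot is
valid when epoch coverage reaches 0.75 (configurable). Non-finite samples
are dropped, with a warning above 5 % per day.

**Diary METs.** An entry contributes to a slot when it overlaps it by at
least half the slot (default; `"any"` overlap selectable) — the source
protocol maps entries "to the corresponding epoch" without stating a rule,
and the half-slot rule avoids double counting at boundaries. Parallel
activities yield three MET levels per slot: `met_low` = minimum MET of the
concurrent set, `met_high` = maximum, `met_avg` = overlap-duration-weighted
mean; a single activity makes the three levels equal (the single-activity
case is not defined by the protocol; equality is this package's choice).
Non-wear entries invalidate their slots outright, for both arms
downstream. The bundled Compendium-style table is an editable CSV of common
activities with approximate values; it claims no authority.

**Inclusion rules.** A day enters the analysis only if the recording spans
the window (start at or before 09:00, end at or after 18:00), carries at
least 9 hours of recorded sensor time, has at least one diary entry, and
has at least four slots valid in both arms simultaneously; participants
need at least 3 included days. "Nine hours of recorded sensor data" is
evaluated as the *sum* of covered time (gaps excluded) by default — the
stricter of the two readings — with the wall-clock span alternative behind
`hours_mode = "span"`. Day inclusion is evaluated per sensor position
independently (a wrist failure does not exclude the ankle arm), which
maximizes usable data.

## Normalization and the correction factor

ENMO is Min-Max normalized separately per sensor position; the three MET
levels are normalized jointly with one shared transformation. Both use
global minima/maxima over all subjects and daytime slots of the *post-QC*
panel — the protocol does not specify whether normalization precedes or
follows QC; post-QC is chosen so the pipeline state is reproducible from
its persisted outputs alone. For the MET pool, slots are deduplicated by
participant–date–slot across sensors.

Group-mean profiles use two-stage averaging (days within participant, then
across participants; SD across participant means), matching a "±1 SD across
participants" presentation; a pooled single-stage variant is available.
`alpha` is fitted per sensor × MET level by minimizing the RMSE between the
group-mean normalized profiles, initialized at the ratio of the two profile
averages. The objective is one-dimensional and quasi-convex with the unique
minimizer `alpha* = sum(M*E) / sum(E^2)` (the closed form ships as
`alpha_closed_form()`, the independent oracle of the simplex fit). The
Nelder-Mead tolerances default to `xatol = 1e-10`, `fatol = 1e-12` —
deliberately tighter than common library defaults (1e-4), because the
package's numerical contract requires oracle agreement to 1e-6 and
machine-level closure of a noise-free cohort; with scipy-style defaults the
simplex may legitimately stop 1e-4 away from the optimum. Per-participant
RMSE pools all jointly valid epochs across a participant's included days
(per-day averaging is exposed as an alternative; neither is claimed as the
original protocol's choice). The alpha-corrected ENMO is clipped at 0 but
not at 1. Even-count medians in the summary tables use the midpoint
convention. Tremor subgroups split at a tremor-item sum of 1
(`<= 1` = no/minimal, `> 1` = stronger), reported for wrist and lower back
by default.

## The synthetic cohort: what it emulates, and what it cannot

The study data this pipeline targets are not publicly deposited, so the
generator replaces them with a *stated world*: 25 participants, 5 days
each, devices worn 08:30–18:30 (the analysis window is 09:00–18:00; a
recording clipped exactly to the 9-hour window would fail the
sum-of-covered-time rule at the first wear gap, so the world records the
waking day, as the original participants did). Each day is a random
partition of the window into 1–6-slot activity blocks drawn from a
nine-context catalogue with latent intensity `u` in [0, 1] (sampling
weights follow a per-participant activity propensity with a midday bump);
every day contains at least one rest block (`u = 0`). Defaults:
`noise_sd = 0.05` per 5-second epoch (in units of the sensor's dynamic
range), `wear_gap_rate = 0.05` per 15-minute span (gaps drop sensor epochs
and emit diary non-wear entries), `tremor_fraction = 11/25` with
`tremor_amplitude = 0.03` g on the wrist of stronger-tremor participants,
raw amplitudes `sensor_amp` = 0.09/0.06/0.05 g (wrist/ankle/lower back) and
wrist `sensor_gain = 1.25`.

Three structural consequences of Min-Max scaling shaped the generator's
design, and are worth stating because they are easy to get wrong:

1. **A multiplicative sensor gain is unobservable.** Min-Max scaling
   removes any affine per-sensor transform, so "wrist amplitudes are
   systematically higher" cannot be emulated by a multiplier alone.
   `sensor_gain` is therefore a *response-shape exponent*: epoch ENMO is
   `sensor_amp * u^(1/gain)`. A gain above 1 is concave — the sensor
   responds disproportionately at light activity (arm movement during
   household tasks), which is the physiologically plausible mechanism —
   and provably yields a strictly smaller fitted alpha: with
   `e = u^(1/g)` and `m = alpha0 * u` on [0, 1],
   `sum(e*(e - u)) > 0`, hence `alpha_hat = alpha0 * sum(u*e)/sum(e^2) <
   alpha0` whenever some `u` is interior.
2. **The largest true level factor must be 1.** Both arms are scaled to
   attain 0 and 1, so exact proportionality `m_L = alpha_L * e` across
   levels forces `max(alpha_L) = 1`. `alpha_true` is therefore
   per MET level with `high = 1` (defaults 0.7 / 0.85 / 1.0), replicated
   across sensors in the ground truth.
3. **The average level is the low/high midpoint.** Every block carries two
   parallel equal-duration activities whose METs are
   `floor + span * alpha_low * u` and `floor + span * alpha_high * u`; the
   duration-weighted mean then fixes `alpha_avg = (alpha_low +
   alpha_high)/2`. Configurations violating these constraints are rejected
   rather than silently reinterpreted, because they would not be
   recoverable truths.

It follows that ground-truth recovery (the zero-noise closure and the
noisy-recovery properties) is only well defined for *matched-response*
sensors, so those tests set all gains to 1; the gain and tremor knobs are
then perturbed separately to check the directional phenomena (wrist needs a
stronger downward correction; stronger tremor raises wrist RMSE). The
generator emulates epoch-scale ENMO statistics, not biomechanics: no gait,
no dyskinesia, no posture transitions, no diary recall error beyond wear
gaps. A green test therefore establishes that the *pipeline* is correct and
well calibrated under its stated world — not that any particular clinical
cohort would produce any particular RMSE table. The raw-signal path
(`raw = TRUE`, and `synthesize_raw_segment()`) synthesizes 100 Hz tri-axial
samples whose band-limited oscillation is calibrated by root finding so the
measured mean ENMO of the emitted waveform hits the latent target; it
exists to exercise the full filter chain and is reserved for small
configurations.

## Numerical choices and degenerate inputs

* Degenerate Min-Max ranges (max = min) map everything to 0 with a warning
  rather than dividing by zero.
* `fit_alpha` requires at least two jointly present slots and a nonzero
  ENMO profile; non-convergence returns the best vertex with
  `converged = FALSE` and a warning instead of failing the run.
* At zero noise the RMSE objective has a kink at its minimum (it is
  `|alpha - alpha*| * rms(E)`); the simplex still converges linearly, which
  is why the `xatol` default is two orders below the required closure
  tolerance.
* Slot and epoch grids are half-open; a sample or entry ending exactly at a
  boundary does not leak into the next slot. Ties in the diary overlap rule
  (exactly half a slot) count as membership (`>=`).
* Empty epochs, empty diaries, days missing one arm, and all-gap days all
  degrade to exclusions with recorded reasons, never to silent zeros.

## Known limitations

* Free-text activity matching is exact/normalized-string only; no fuzzy or
  NLP mapping, and no dual-rater consensus emulation.
* The per-sensor/per-level true factors of the generator are constrained by
  Min-Max identifiability (above); dataset-specific published correction
  factors cannot be reproduced without the non-public cohort.
* Statistical testing between positions or subgroups is out of scope; the
  outputs are descriptive (medians, ranges, profiles), as in the protocol
  this package operationalizes.
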