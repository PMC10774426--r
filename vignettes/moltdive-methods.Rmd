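---
title: "Methods: detecting at-sea behavior and ingestion events in molting seals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting at-sea behavior and ingestion events in molting seals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltdive)
```

## The problem

Molting elephant seals carry three sensors sampled every 10 s: a
time-depth recorder with light-level and wet/dry channels, and a stomach
temperature pill (STP). From these four channels the package answers two
questions per individual: *when was the animal in the water, and doing
what* (diving, surface swimming, or soaking in a mud wallow), and *when
did it ingest something, and was it water or prey*. Everything downstream
— cohort tables, the PCA swimming score, hyperthermia/at-sea latencies —
is descriptive aggregation of those two event streams.

## Behavioral detection from depth, wet and light

A **submerged phase** is a maximal run with depth > 0.5 m while the
wet/dry sensor reads wet. Depth is first re-zeroed against a known
on-land interval (`zero_offset_correct()`, median offset, idempotent).
Phases are classified in this order:

1. **Wallow** if the light-level range over the phase is ≤ 5 instrument
   units. Mud is opaque: the sensor sees near-constant darkness however
   deep the animal sits. Sea water is not: light decays roughly
   exponentially with depth, so any real submersion modulates the signal.
2. **Dive** if maximum depth > 5 m.
3. **Surface swim** if maximum depth lies in [1, 5] m. Consecutive swim
   phases separated by ≤ 20 min at the surface merge into one event.
4. Phases shallower than 1 m that are not wallows are discarded as splash.

Dives get a descent / bottom / ascent segmentation at 80% of maximum
depth — the conventional dive-analysis boundary; the three phases
partition the dive, and ties for the maximum resolve to the earliest
sample. Events of one kind chain into **cycles** while surface gaps stay
under 20 min (the observed surface-interval distribution breaks around
17 min); isolated events count as singleton cycles, matching how cycle
tables are reported in the field.

### Why the wallow rule uses the raw light channel

`remove_diel_light()` removes the day-night cycle by classical seasonal
decomposition (moving averages, 24-h period, ≥ 48 h of record required —
shorter records are excluded, as in the field protocol). That adjustment
is the right tool for asking "did light vary because of depth rather than
time of day" over a *sea* event. For a *mud* event it does the opposite:
the raw channel is flat, so subtracting the average diel pattern injects
up to tens of units of spurious variation into a dawn or dusk wallow
(the diel slope reaches ~0.013 units/s; over a 30–60 min wallow that is
23–47 units). The wallow discrimination therefore uses the raw channel
by default (`dive_config(light_channel = "raw")`); the adjusted channel
is still computed and available, and the config switch exposes the
alternative.

## Stomach-temperature quality control

Run before event detection, in this order:

* **Post-capture discard**: the first 6 h after capture are dropped
  (anesthesia effects).
* **Pill loss**: the stomach channel is truncated at the start of the
  first run of identical readings (at the 0.1 °C instrument resolution)
  lasting ≥ 3 h. Constancy is judged at instrument resolution, not
  floating-point equality.
* **Outliers** (`remove_outliers()`): deviations from a centered 15-min
  rolling mean are screened with Tukey fences (Q1 − 1.5 IQR, Q3 + 1.5 IQR
  over the whole deployment), with two refinements. A deviation must also
  exceed the pill's stated accuracy (0.3 °C) — Tukey fences alone flag
  ~0.7% of pure Gaussian noise, which would mostly delete good data — and
  only excursions lasting ≤ 30 s qualify. The duration cap is what
  separates measurement spikes from biology: an ingestion drop deviates
  from the rolling mean for many minutes, a pill glitch for a sample or
  two. The rolling baseline is re-fitted after masking so a gross spike
  cannot drag its window neighbours over the fences. Flagged samples
  become `NA`; nothing is interpolated.
* **Drift** (`assess_drift()`): the channel is downsampled by a factor of
  100 (one sample per ~17 min), association with time is measured by
  Kendall's τ and the trend by the Theil–Sen median-of-pairwise-slopes
  estimator — the standard robust companion to τ. The report exposes both
  the raw per-step slope and its rescaling to °C per 10 days, and never
  applies a correction: at ~0.1 °C per 10 days the drift is below the
  pill accuracy over a one-week deployment.

## Ingestion events

An ingestion appears as a sharp decline followed by a roughly exponential
recovery. Anchors:

* **T2** — each local minimum below 36.5 °C (the lowest core temperature
  described for elephant seals) seeds a candidate.
* **T1** — scanning backward from T2, the last sample whose 2-min local
  slope is below 0.005 °C/s; its value is averaged over that window to
  suppress single-sample noise. Candidates whose drop T1 − T2 is smaller
  than 0.5 °C are treated as noise: with a ±0.3 °C instrument, smaller
  drops are not interpretable.
* **T3** — the first sample after T2 from which temperature stays at or
  above T1 − 0.3 °C (the pill accuracy) for at least 10 min. The band is
  one-sided: overshooting the baseline still counts as recovered, which
  keeps T3 well-defined when the animal enters the (0.6 °C warmer) sea
  mid-recovery.

Double ingestions — a second drop before the first recovery completes, or
two drops separated by under 10 min — merge into one event that keeps the
global minimum as T2 and counts its components in `merged_from`; distinct
descents inside a single sub-36.5 °C excursion are counted the same way.
Implausible candidates are flagged `anomalous` and kept for audit, never
silently dropped: minimum below 20 °C, recovery non-monotone by more than
1 °C after the last sub-minimum (the signature of pill measurement
error), non-positive drop, or no recovery before the record ends. The
flagging automates what is usually a visual screen. Note that a *fast
initial drop* is deliberately not a flag: genuine ingestions are
sharp-decline events, often completing within one 10-s sample.

### Features and their anchors

With Δ*T* = *T1* − *T2* and *T*~0.5~ = *T2* + Δ*T*/2:

* **t~0.5~** — time from the beginning of the decrease to the (linearly
  interpolated) upward crossing of *T*~0.5~. When the decline spans more
  than one sampling interval the decrease begins at *T1*; when it is
  unresolved at the cadence (a single-step drop) the decline is taken to
  occur at the minimum sample itself. The drop instant of a one-sample
  decline is unknowable to better than one cadence, and anchoring it at
  the recorded minimum makes t~0.5~ agree with the closed form ln 2/*k*
  for an exponential recovery at any rate — sub-cadence interpolation is
  what lets a 10-s instrument resolve a 69-s half-recovery to better than
  2%.
* **Index I** = t~0.5~/Δ*T* (s/°C), the rate-of-recovery index used to
  separate prey (slow recovery per degree) from water.
* **t~rec~** = t(*T3*) − t(*T2*).
* **Integral** — area above the curve by the trapezoid method. The
  default (`integral_method = "asymptote"`) measures the area from the
  recovery asymptote, approximated by *T1*, and completes the tail beyond
  *T3* nonparametrically as (remaining deficit) × t~0.5~/ln 2 — the exact
  tail for an exponential recovery, using the observed half-recovery time
  as the time constant, with no curve fitting. Truncating at *T3* instead
  (`"truncated"`, also available) discards a tail of ε/k + ε·t(T3) that
  reaches 20–60% of the true area Δ*T*/*k* for slow recoveries with the
  0.3 °C baseline band, which would make the integral incomparable across
  recovery rates; the completed version recovers Δ*T*/*k* to within ~5%
  across the whole plausible parameter range.

Classification applies four independent published thresholds, each
strict (boundary values label water): I > 250 s/°C, integral >
3000 s·°C, t~rec~ > 35 min, Δ*T* > 4.7 °C.

### Hyperthermia

The threshold is the individual's 97.5% quantile of on-land stomach
temperatures, computed after excluding detected ingestion spans (a deep
drop would otherwise distort the distribution); on-land runs strictly
above it lasting over 1 h become events. The quantile is per-individual —
baselines differ by a few tenths of a degree between animals — rather
than pooled. Latency to the next at-sea event is reported per
hyperthermia event; two events may share one subsequent excursion.

## Context linking

Each ingestion is assigned the behavior containing its thermal minimum
T2 — the instant closest to the ingestion itself (T1 anchoring is a
config switch): inside a dive → `diving`; inside a surface swim →
`surface_swimming`; inside a wallow or dry → `on_land`; wet with no
detected submersion → `unknown`. Day/night uses geometric solar elevation
(> 0 = day, no twilight allowance) from a standard NOAA/Meeus
low-accuracy solar position, accurate to ~0.01°, far below the minutes of
timing accuracy the diel split needs.

## Summaries

`summarize_behavior()` and `cohort_summary()` reproduce the standard
mean (sd) min–max cohort tables: per-dive metrics are pooled over all
dives, per-individual metrics over individuals, "at-sea events per day"
counts excursions (cycles). The PCA swimming score is a centered-scaled
`prcomp` over number of dives, number of surface swims and mean event
duration; the sign indeterminacy is fixed by requiring a positive PC1
loading on the number of dives (PC2: largest-magnitude loading positive).
BMI uses mass/length² (the exponent is configurable, since condition
indices vary in this choice); specific mass loss is daily loss per unit
initial mass.

## The simulator and what passing tests mean

`simulate_individual()` lays out non-overlapping behavioral blocks on the
10-s grid and renders all four channels consistently. Its defaults are
the study conditions the analysis targets: 7-day records; lognormal dive
depths (mean ≈ 12.5 m, truncated to 5–43 m) and durations (mean ≈
7.7 min) in cycles of geometric mean size 8.6 with 2-min-scale surface
intervals; multi-hour surface swims at 1.2–4.5 m; 20–60 min optically
dark wallows; land baseline ≈ 36.5 °C (individual spread 0.15 °C), sea
offset +0.6 °C with a 5-min transition constant; sensor noise 0.05 °C;
drift 0.05 °C per 10 days; ingestions by instantaneous mixing
(T2 = (M·T1 + m·T~w~)/(M + m), stomach mass 5 kg, water at 8 °C) with
single-exponential recovery — fast rates (1/450–1/250 s⁻¹) for water,
slow (1/2000–1/900 s⁻¹) for prey — placed 15% in dives, 50% in swims,
35% on land; and trapezoidal on-land hyperthermia excursions (+1.5 °C,
~110 min, 15-min conduction ramps — a rectangle's falling edge would
mimic an ingestion drop, which real heat diffusion does not).
Light is rendered as (night floor 40 + diel amplitude 180 ×
sin(solar elevation)) × exp(−0.3 × depth), clamped to a 2-unit band in
mud, so the 5-unit wallow rule is separable by construction *and* night
submersions remain detectable against the ambient floor.

The mixing/exponential model gives every event feature a closed form
(t~0.5~ = ln 2/k, integral = ΔT/k), which is what makes the feature
pipeline testable against analytic oracles rather than against itself.
What the simulator deliberately does not emulate: depth quantization of
real TDRs (0.5 m resolution), gradual multi-sample ingestion declines,
non-exponential (biphasic) recoveries, overcast-sky light variability,
and Argos positioning. Passing the recovery tests therefore demonstrates
the pipeline is correct *under its stated event model*, not that the
thresholds are optimal for field records.

Determinism: one `set.seed()` per individual; cohort members get seeds
from a fixed affine hash of the master seed, so any individual
regenerates independently.

## Numerical choices and degenerate inputs

* Timestamps are UTC; intervals half-open [start, end); a run of *k*
  samples spans (*k* − 1) × cadence.
* Cadence gaps are flagged, never interpolated.
* Kendall's τ of a constant channel is defined as 0 (no trend), avoiding
  the 0/0 of the rank correlation.
* Theil–Sen on a noise-free ramp equals the ramp slope exactly; this is
  asserted in the tests.
* The seasonal decomposition refuses records under 48 h (two full diel
  periods), mirroring the exclusion of short deployments.
* `swimming_score()` refuses cohorts under 3 individuals and names any
  zero-variance column instead of silently producing NaNs.
* Problem sizes in the test suite (5 × 7-day simulated individuals for
  the end-to-end recovery checks; 8-day series for drift; 36-h ramps for
  the hyperthermia quantile logic) are chosen as the smallest records in
  which each rule's preconditions are comfortably met — e.g. drift needs
  48 h after downsampling, and the hyperthermia quantile needs the
  excursion to occupy well under 2.5% of the on-land time.

## Known limitations

* The wallow rule depends on ambient night light exceeding the 5-unit
  range at swim depths; truly dark nights would push night swims into
  the wallow class for any light-based rule.
* Context is `unknown` whenever wet contact lacks a detected submersion;
  tidal-zone ingestion cannot be separated from shallow splash.
* The integral's tail completion assumes the recovery stays roughly
  exponential past T3; strongly biphasic recoveries would be
  under-integrated.
* Hyperthermia and ingestion detection interact (each excludes the
  other's spans); a drop occurring *inside* a hyperthermia excursion is
  anchored against the elevated baseline.
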