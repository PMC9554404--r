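---
title: "From raw wrist acceleration to guideline adherence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw wrist acceleration to guideline adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristpa)
```

`wristpa` turns raw tri-axial wrist acceleration (nominally 50 Hz, ±8 g)
into daily physical-activity metrics and four adherence flags: the 2010 WHO
guideline (≥ 30 min/day of MVPA in bouts of ≥ 10 min), the 2020 WHO
guideline (≥ 30 min/day of MVPA of any bout length), and ≥ 7,500 and
≥ 10,000 steps/day. This vignette documents the model behind each stage,
the tunable constants and why they have the defaults they do, what the
synthetic-signal generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Signal model and intensity metric

A worn accelerometer measures gravity plus body acceleration. The intensity
metric is ENMO, the Euclidean norm minus one gravity, negative values
truncated to zero, in milligravity (mg):

$$\mathrm{ENMO}(t) = \max\!\left(0,\ \sqrt{x^2+y^2+z^2} - 1\,\mathrm{g}\right)\times 1000 .$$

ENMO is averaged over 5-s epochs on a grid aligned to local midnight, so a
day is exactly 17,280 epochs and day boundaries are exact ("midnight to
midnight"). Partial epochs at recording edges are dropped rather than
padded, which keeps per-day epoch counts exact; partial *days* are padded
with non-wear epochs before summarisation so that every summarised day
spans the full grid. Epoch intensity uses the wrist cut-points
< 25 mg (inactive), 25–99 mg (light), ≥ 100 mg (MVPA), with a vigorous
sub-band at 400 mg — the 400 mg value is a toolchain convention, exposed in
`wpa_config()$bands` because no single published value governs it.

Timestamps are timezone-naive local time; no daylight-saving handling is
attempted (a documented limitation — the generator never crosses a DST
change). The raw interface is a documented CSV dialect
(`time,x,y,z`, ISO-8601 + g units) rather than a proprietary binary
container; any other reader can be added behind the same `raw_recording`
contract. Grid gaps up to 1 s are filled by holding the last sample; longer
gaps are refused — device gap behaviour is undocumented, so a conservative
stand-in was chosen.

## 2. Autocalibration

During still periods the measured vector should lie on the 1 g gravity
sphere. Still windows are non-overlapping 10-s windows whose three per-axis
SDs are all below 13 mg (values follow the raw-accelerometry calibration
literature; both are in `wpa_config()$calibration`). The per-axis
offset/gain model `corrected = (sample − offset)/gain` is fitted by an
iterative procedure: project current corrected still points onto the unit
sphere, regress each axis of the projection on the corrected value
(weighted to down-weight points far from the sphere), fold the fit into the
cumulative parameters, and stop when the mean absolute norm error changes
by < 0.001 mg (at most 1,000 iterations).

Degenerate geometry is guarded: if the still points span < 0.3 g of range
on any axis (fewer than about three distinct orientations), the fit is
ill-posed and the identity model is returned with `converged = FALSE`;
likewise if the fit fails to reduce the error. Validation injects a 5 × 5
grid of offsets (±50 mg) and gains (0.95–1.05) into 8-orientation still
data with 2 mg noise; offsets are recovered within ±2 mg and gains within
±0.005 in every cell.

## 3. Non-wear and sleep

Non-wear uses 60-min windows advanced in 15-min steps from the recording
start. A window votes non-wear when at least 2 of 3 axes have SD < 13 mg
*or* range < 50 mg; an epoch is non-wear if any covering window votes so.
The 60/15 geometry is the documented configuration; the axis-vote constants
follow the non-wear literature rather than any single source, and all four
numbers are config keys. Consequences worth knowing: a still block shorter
than 60 min can never be flagged (no window fits inside it), and boundary
resolution is the 15-min slide, so flagged boundaries are correct to
≤ 15 min.

The sleep period is found per noon-to-noon night from the arm angle
`atan(z̄ /√(x̄² + ȳ²))` computed from epoch-mean axes (the difference from a
median-of-medians formulation is negligible at 5-s resolution). For each
5-min block the mean absolute successive z-angle difference is computed;
blocks below a data-driven threshold — 15 × the night's 10th percentile,
floored at 0.1° and capped at 15° — form sustained-inactivity runs, runs
separated by < 60 min are merged, and the longest merged run of ≥ 30 min is
the night's sleep period. This is a simplified member of the
heuristic-angle family and is deliberately excluded from adherence logic
(it feeds only descriptive summaries). Its known failure mode is inherited
from the relative threshold: in a noon-to-noon window with *no* genuinely
still night (e.g. a schedule whose nights are device-off, or an evening-only
recording edge), the 10th percentile is taken from ordinary quiet sitting
and the window's most sedate stretch is labelled sleep. On real recordings
with a nightly rest this is benign; on schedules without one, `sleep_min`
should be ignored.

## 4. MVPA accrual and bout detection

Two accrual semantics are implemented because the phrase "accrued in 1-min
bouts" is genuinely ambiguous at 5-s resolution — this is the single most
consequential ambiguity in the chain:

* `epoch` (default): class minutes = qualifying wear epochs / 12. This
  matches the time-in-intensity behaviour of the raw-accelerometry
  toolchain this package follows.
* `minute80`: a minute is MVPA only when ≥ 80 % of its 12 epochs qualify;
  minutes failing that are light when light-or-above epochs outnumber
  inactive ones, else inactive.

Both are exposed via `wpa_config()$accrual$mode`; all validation uses the
default.

The 2010-guideline bout rule is: an interval of ≥ 120 epochs whose
above-threshold (≥ 100 mg) fraction is ≥ 0.8, both ends above threshold.
The published rule does not fix an algorithm, so the package pins the
semantics with a greedy left-to-right scan: a candidate starts at an
above-threshold epoch and extends while (a) the running above fraction
stays ≥ 0.8 at every position and (b) no run of > 1 min of consecutive
below-threshold epochs occurs; the candidate is trimmed to its last
fraction-satisfying above epoch. Non-wear epochs count as below threshold
(conservative: the device must be worn to earn bout credit). The reference
semantics is defined by an exhaustive interval-enumeration oracle in the
test suite; the scanner is required to agree with it exactly on 1,000
random epoch sequences, so any future change must preserve oracle
agreement. Two provable invariants are also asserted: bouted minutes
≤ MVPA minutes / 0.8, and (under epoch accrual) M30 ≥ 100 mg ⇔ MVPA ≥ 30
min/day.

MX metrics (M2/M30/M60) are the (X·12)-th largest epoch ENMO of the day,
with non-wear epochs counted as 0 mg (again conservative — no phantom
activity). The imputed 24-h mean acceleration averages all 17,280 epochs,
replacing non-wear epochs by the participant's mean wear ENMO at the same
clock epoch over the other valid days, falling back to 0 without donors.

## 5. Step counting and cadence

Steps are detected on the magnitude signal resampled to 15 Hz (linear
interpolation; the cited implementation lineage's convention, which also
stabilises peak windows at gait frequencies). Candidate peaks are maxima of
a centred 3-sample window with magnitude ≥ 1.2 g; peaks are chained when
their spacing is 5–15 samples (cadence 60–180 steps/min at 15 Hz) and their
amplitudes differ by ≤ 0.5 g; only chains of ≥ 4 peaks with local variance
≥ 0.001 g² survive, and each surviving peak is one step. The originally
validated parameter set for this detector family is study-internal and
unpublished, so all eight values are exposed in `step_detector_params()`
and results must be read as parameter-dependent; validation uses the
defaults. Mean 24-h cadence divides by the fixed 1,440 minutes (not wear
minutes), as does the percentage of zero-cadence minutes; peak-1/30/60
cadence averages the highest minutes without requiring them to be
consecutive.

## 6. The synthetic generator: what it emulates and what it does not

Every stage is validated against generated recordings with exact truth.
The measurement model per activity kind:

* **walk** — the gravity direction scaled by `1 + w(t)` with
  `w = A·(0.5 + 0.5 cos θ)²` (a DC + fundamental + one-harmonic pulse), θ
  advancing at cadence/60 Hz. The pulse peaks exactly once per gait cycle
  (one true step), has peak amplitude `A` and time-mean `0.375·A`, so the
  expected epoch ENMO is `375·A` mg — the 0.375 constant is analytic, fixed
  once, and frozen. Amplitude ≥ 0.3 g at cadence ≥ 100 yields ≥ 112 mg,
  safely in the MVPA band; amplitude 0.24 g yields 90 mg, a "stroll":
  detectable steps with light-intensity ENMO. A mean-reverting per-epoch
  orientation wobble emulates arm swing without touching the magnitude
  (hence neither ENMO nor step truth).
* **sedentary / light** — gravity at a tilted base orientation with AR(1)
  orientation wobble, posture shifts, and axis noise of 25 / 90 mg SD
  (expected ENMO ≈ 10 / ≈ 40 mg: the inactive and light bands).
* **sleep** — near-still (5 mg noise) with posture changes every 15–25 min:
  still enough for minimal z-angle variability, but never 60 min of
  flatline, so sleep is not mistaken for non-wear.
* **nonwear** — an exactly constant gravity vector plus quantisation-scale
  noise (0.3 mg SD).

Truth is defined by the schedule, not by re-running the pipeline: true
MVPA seconds are the seconds generated in the ≥ 100 mg expected band, true
bouted seconds are those inside continuous walk blocks ≥ 600 s, and true
steps are generated gait cycles. Device miscalibration (per-axis
gain/offset) is applied *after* truth is recorded. The gait model is a
two-harmonic waveform, not a biomechanical simulation: it exercises the
detector's magnitude, periodicity, similarity and continuity filters while
keeping truth exact, but it does not reproduce free-living signal
complexity — double support variability, surface changes, arm gestures
superimposed on gait. Passing tests therefore demonstrate algorithmic
correctness against the stated rules, not field accuracy on patients.

The reference validation cohort (`cohort_spec()` defaults) encodes the
mechanism that separates the two WHO criteria: 20 participants, 20 % "bout
exercisers" (one 45-min brisk walk per day — a single qualifying bout) and
80 % "accumulators" (ten 4-min brisk walks — the same MVPA volume, no
qualifying bout), each with tiered stroll volume so daily steps straddle
the 7,500 and 10,000 thresholds. The designed prevalences are exactly
100 % (2020), 20 % (2010), 80 % (≥ 7,500) and 40 % (≥ 10,000), giving the
qualitative ordering P(2020) > P(7,500) > P(10,000) > P(2010) that a
sporadically active cohort produces. Eight recorded days (day 2 to day 9
after the intervention, day 0 being the procedure) of 16 h wear at 50 Hz
satisfy the ≥ 7-valid-day inclusion rule with margin. Walks are noiseless
in this cohort (`walk_jitter = 0`) and no miscalibration is applied, so
end-to-end flag agreement is required to be exact; sedentary/light/sleep
blocks keep their intrinsic noise because that noise *is* their signal.
Archetype parameters are chosen for mechanism coverage, not cohort realism
— no signal-level description of the study population exists to imitate.

## 7. Aggregation, inclusion and reporting

A valid day has ≥ 12 h wear; days are counted from index 2 (recordings
start the evening of discharge, so earlier days are incomplete and
unevenly available). Participants with ≥ 7 valid days are included;
per-participant metrics are arithmetic means over valid days, and all four
adherence boundaries are inclusive (`≥ 30 min`, `≥ 7,500`). Day-level
adherence curves condition on the day being valid — an assumption, since
the day-level denominator is not otherwise pinned down. Cohort tables
report medians with first and third quartiles using the
linear-interpolation quantile convention (`type = 7`; the convention is a
documented choice). Between-group comparisons use the two-sided Pearson
chi-square without continuity correction, replaced by Fisher's exact test
when any expected cell is below 5 — a conventional choice where only a
significance flag is specified; the test-suite property ties the analytic
p-value to a 2×2 label-permutation law (hypergeometric, mid-p for lattice
ties) within 0.01. The age split uses the median age of included
participants. Regressions are ordinary least squares of each MVPA
definition on mean daily steps and on peak-30 cadence, reporting r, R² and
the predictor value at the 30-min crossing, defined only for positive
slopes.

## 8. Numerical choices and degenerate inputs

* Epoch grid cells are half-open; a step event exactly on an epoch
  boundary belongs to the later epoch.
* The bout scanner's fraction comparisons use `count ≥ 0.8 · length`
  directly; the oracle uses the same comparison, so ties at exactly 80 %
  qualify.
* `estimate_calibration` falls back to the identity whenever it cannot
  reduce the error or leaves the plausible gain range (0.9, 1.1).
* Zero-variance predictors and excluded participants raise errors rather
  than returning NA silently.
* Recordings are processed one participant at a time (an 8-day 50 Hz
  recording is ~0.8 GB as a double matrix); chunked signal statistics are
  computed in compiled code.

## 9. Problem sizes used in validation

The shipped validation uses: 1,000 random epoch sequences (length ≤ 360)
for bout-oracle agreement; a 3 × 3 cadence × amplitude grid of 3-min walks
for step recovery (tolerance ±5 %, absorbing edge losses of the continuity
filter); a 5 × 5 calibration grid; still blocks of 45/60/90/180 min for
non-wear; 500 random days for the metric dualities; the 20-participant
reference cohort end to end; and n = 200 planted-structure regressions.
These sizes make the full suite run in minutes on a single CPU while
keeping every check at the study's native sampling rate and day span.

## 10. Known limitations

* Cycling and other low-wrist-movement activities are under-counted by
  design of wrist-worn step detection; the package does not attempt to
  correct this.
* The sleep heuristic's relative threshold misbehaves in windows without a
  genuine night (Section 3).
* The step detector's parameters are defaults of the open-source lineage,
  not a tuned clinical configuration.
* No timezone/DST handling; no imputation of raw signal beyond 1-s gaps.
* The generator's activity archetypes are stylised; they bound what the
  validation can claim about free-living data.
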