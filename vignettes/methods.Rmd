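---
title: "Estimating Parkinson's motor symptoms from five-device IMU recordings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Parkinson's motor symptoms from five-device IMU recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Motor fluctuations in Parkinson's disease — resting tremor, bradykinesia,
levodopa-induced dyskinesia, gait impairment, freezing of gait (FoG) and the
medication OFF state — vary over the day and between days, and a half-hourly
clinical examination cannot follow them at home. `pdmotor` implements a
monitoring pipeline that turns synchronized recordings from five body-worn
inertial units (both wrists, both ankles, waist; tri-axial accelerometer,
gyroscope and magnetometer at a nominal 59.5 Hz) into per-30-minute estimates
of each symptom on familiar clinical scales, together with the statistical
machinery used to validate such estimates against expert ratings
(ROC-selected operating thresholds, confusion metrics, Bland–Altman
agreement, day-to-day ICC).

Because real patient recordings of this kind are proprietary, the package
also ships a first-class synthetic-signal simulator with per-window ground
truth. Everything the pipeline claims is demonstrated on that simulator; the
section on its limitations below states explicitly what this does and does
not show about real data.

# Pipeline

## Windowing and units

Streams are synchronized by linear interpolation onto a uniform grid at the
nominal rate, starting at the latest common start time (the method is
idempotent on already-uniform input). The basic analysis window is 4 s;
wrist-tremor analysis uses 3-s windows; results are aggregated into
half-open 30-minute bins aligned to the recording start, a window belonging
to the bin containing its start sample. Signals are carried in device-native
units (g, deg/s, gauss) end to end: every clinically meaningful constant in
the pipeline — tremor amplitude anchors, movement-speed thresholds, device
full scales — is conventionally stated in those units, so an internal SI
conversion would only create a second unit system with no consumer
(`gToMs2()`/`dpsToRads()` are provided for interoperability). Magnetometer
channels are ingested and validated against the +-16 gauss full scale but
deliberately unused by the estimators, which rely on accelerometer and
gyroscope features only.

## Motion features

Per 4-s window the feature table contains, for each position and channel,
the mean, standard deviation, signal energy and zero-crossing rate; a jerk
RMS per accelerometer triplet; the pairwise correlation of gyroscope
magnitudes between positions (movement coordination: walking is coordinated,
dyskinesia is not); and gyroscope band energies in the bins (0–1], (1–3],
(3–8], (8–12], (12–Nyquist] Hz, chosen to straddle the voluntary (< 3 Hz),
tremor (3.5–8 Hz) and freeze-relevant bands. That is 220 named features —
the exact production roster of such devices is not public, so this schema is
a documented reconstruction of the stated feature families, deliberately
larger than the "over 140" it needs to cover. All spectra are Hann-windowed
periodograms summed over the three axes of a sensor; the magnitude envelope
is never used for spectra because rectification doubles the apparent
frequency of an oscillation.

## Activity detection

A Gaussian Naive Bayes classifier assigns each window to {Walking, Resting,
Tremor, Dyskinetic, Other}. Features are chosen by greedy forward wrapper
selection maximizing leave-one-subject-out accuracy; selection stops when no
candidate improves accuracy or at 20 features, with ties broken by schema
order so the procedure is deterministic. Two computational choices make the
wrapper affordable: the Naive Bayes log-posterior is additive over features,
so each candidate is scored by adding one cached per-fold log-density matrix
to the running log-posterior; and selection operates on a per-subject,
per-class evenly-spaced subsample of training windows (default cap 120),
while the final model is always fit on all training windows and evaluated on
all held-out windows. Class-conditional variances are floored at 1e-6 of the
pooled variance. "Leave-one-out" is implemented as leave-one-*subject*-out
throughout: window-level cross-validation would leak within-subject signal
correlation into the accuracy estimate.

Posture (standing / sitting / lying) is read from the gravity inclination of
the waist and shank accelerometers in quasi-static windows: waist tilted
more than 60 degrees from vertical means lying; waist upright with a
horizontal shank means sitting; otherwise standing. Non-static windows fall
back to "standing" flagged low-confidence.

## Tremor

Wrist tremor is detected in 3-s gyroscope windows by a small CART tree over
five spectral features: the tri-axial energies of the < 3 Hz (voluntary) and
3.5–8 Hz (tremor) band components, their ratio, the dominant in-band
frequency, and the sharpness of that spectral peak. The tree (depth <= 4,
minimum leaf 20) is trained on a labeled synthetic corpus of rest noise,
voluntary movements (sinusoids *and* harmonic-rich discrete pulses) and
modulated tremor oscillations, then frozen as a portable node table in
`inst/extdata/tremor_tree.yaml` so inference is deterministic and
independent of the training machinery. Amplitude is the RMS of the 3.5–8 Hz
band-passed tri-axial signal, mapped to the 0–4 UPDRS item-20 scale by a
piecewise-linear ("fuzzy linear") map with anchors 0, 5, 15, 35, 60 deg/s
RMS for scores 0–4 (config-overridable). The 30-minute score is the mapped
median amplitude over detected windows, forced to zero when tremor occupies
less than 25% of the bin (the constancy gate). Tremor evaluation is gated to
windows whose activity label is Resting, Other — or Tremor itself: the gate
exists to exclude walking, dyskinetic and voluntary motion, and the Tremor
class *is* rest with tremor present, so excluding it would discard the very
windows being scored. Leg tremor is reported two ways: the mean Tremor-class
posterior over the bin (the quantity thresholded at 0.16), and per-ankle
scores from the same 3-s spectral machinery applied to the ankle gyroscopes.
Action and kinetic tremor are out of scope.

## Gait and freezing of gait

Consecutive Walking windows are merged into walking regions, bridging gaps
of one window and discarding regions shorter than 8 s. Step events are read
off the 6-Hz low-passed shank medio-lateral angular velocity: per cycle a
positive swing peak (maximum rotational speed, RS) flanked by negative peaks
at terminal contact (TC, heel off) before and initial contact (IC, heel
strike) after, with the TC < RS < IC ordering enforced. Gait features per
region: shank sagittal range of motion (integrating the angular velocity
between consecutive TCs with per-cycle linear drift removal), cadence
(steps/min, twice the stride rate of one shank), mean swing time (TC to IC)
and its coefficient of variation. A linear model on the standardized
features maps them to the UPDRS item-29 scale, clipped to [0, 4]; the RoM
coefficient is negative and dominant, so the score strictly increases as
RoM shrinks. The shipped coefficients were fit by least squares on the
default synthetic cohort's region-features-versus-generated-severity pairs
(`tools/calibrate.R`), and `fitGaitModel()` refits them on any labeled data.

FoG is evaluated on pauses of 2–10 s immediately preceding a walking-region
start. The freeze index is the 3–8 Hz to 0.5–3 Hz power ratio of the shank
gyroscope spectrum, with the denominator floored at 1e-6 of total power. An
event requires the index to exceed 2 on *both* shanks, actual trembling
power on both (freeze-band RMS above 5 deg/s), and pause windows not labeled
Tremor or Dyskinetic — the discrimination clause that keeps wrist tremor or
dyskinesia during a pause from masquerading as freezing. The session score
is events / candidate pauses, also reported per bin; the 0.02 operating
threshold separates simulated freezers from non-freezers. Full akinetic
motor blocks (freezing without trembling) are explicitly not detected.

## Dyskinesia and bradykinesia

Dyskinesia is scored on 5-minute intervals with walking windows removed
(entirely-walking intervals are excluded). An interval is dyskinetic when
the mean Dyskinetic posterior over its remaining windows exceeds 0.35 — a
deliberately sub-majority gate, because dyskinetic expression is
intermittent within five minutes — and its severity is the mean multi-limb
1–4 Hz gyroscope band RMS scaled onto the device scale. The scale factor is
calibrated so the generator's AIMS>4 boundary lands at the 1.66 operating
threshold. The 30-minute score averages the scored intervals of the bin.

Bradykinesia starts from discrete movement events: supra-threshold bursts of
the smoothed (0.25 s) gyroscope magnitude with 40/20 deg/s on/off
hysteresis, 0.2–5 s duration, fully inside Resting/Other-labeled spans; peak
speed is read off the raw magnitude (the smoothed envelope would shave short
pulses). The normative speed is the 5th percentile of the pooled control
cohort's peak speeds; the 30-minute score is the percentage of events slower
than that norm, `NA` when the bin has no movements.

## OFF-state estimation

The per-bin symptom vector has 12 entries in fixed order: lack of movement
(fraction of windows with mean gyro power below 25 (deg/s)^2), activity
level (mean gyro power), resting time (fraction of Resting windows), gait
score and gait score excluding dyskinetic intervals, four per-limb tremor
scores, the FoG ratio (standing in for the postural-instability group), and
two per-wrist bradykinesia scores. A two-class Gaussian Naive Bayes
estimates P(OFF); missing entries (for example gait in a bin without
walking) are omitted from the likelihood product, never imputed — a strict
complete-case filter is also available for validation parity. OFF detection
uses the 0.5 threshold; OFF *time* is the fraction of valid bins with
P(OFF) strictly above 0.55. Feature importance uses ReliefF (k = 10 nearest
hits/misses, all complete instances, min-max scaled features) with group
aggregates as the mean of member-feature weights.

# The simulator: what it emulates and what it does not

`simulateRecording()` composes, per scheduled bout: pink (1/f) sensor noise
(0.02 g RMS accelerometer, 1 deg/s RMS gyroscope), posture-dependent gravity
with small orientation wobble; rest tremor as an amplitude-modulated
sinusoid at the profile's 3.5–8 Hz frequency plus a 0.4-amplitude second
harmonic, present in a rest bout with state-dependent probability (0.8 OFF /
0.4 ON, its constancy); walking as per-stride shank angular-velocity
templates (positive swing lobe flanked by negative TC/IC lobes, scaled so
the integrated angle range equals the commanded RoM, with stride-time
jitter), plus arm swing and waist bob; dyskinesia as 1–4 Hz sinusoid-mixture
angular motion on at least two limbs, independent across limbs, amplified in
ON and suppressed in OFF (the one symptom medication *induces*); discrete
wrist movements as squared-sine velocity pulses whose peak speed scales with
the movement-speed multiplier (reduced in OFF); and pre-walk freezing bursts
(3 s of 3–8 Hz trembling on both shanks) emitted with probability
propensity x state multiplier. Among the OFF effects, gait deterioration
(range-of-motion down to 0.60 of baseline) is deliberately the strongest,
with movement slowing moderate (speed x0.8): this cohort emulates a
population in which the postural-instability/gait cluster is the dominant
OFF correlate, which is also the regime the OFF-importance analysis is
meant to exhibit. Bout durations are multiples of the 4-s
window and ON/OFF states change only on 30-minute boundaries, so no analysis
window or bin ever straddles a ground-truth transition. Annotations (UPDRS
items, AIMS, diary) are derived from the true severities through the same
anchor tables the forward estimators use, which makes parameter recovery
well-posed *by construction*.

That last sentence is the key caveat: passing the recovery and accuracy
tests shows the pipeline is internally consistent and correctly implemented,
not that it would reach the same numbers on real patients. The simulator has
no sensor drift or artifacts, no soft-tissue motion, no stair climbing or
turning, no postural-transition transients, clean class boundaries, and
annotation noise exactly matched to the forward maps. Class-separability on
synthetic data is optimistic; the leave-one-subject-out protocol removes
subject leakage but not this generative optimism.

The default cohort — 10 patients + 5 controls, 2 days x 4 h at 59.5 Hz,
master seed 42 — is the condition under which every cohort-level property in
the test suite is stated. It was sized to keep a full single-pass cohort run
(simulation, features, LOSO evaluation, symptom tables) in the tens of
minutes on one CPU; `cohortFeatureTable(withInputs = TRUE)` collects the
label-free symptom inputs alongside the features precisely so the cohort is
simulated once, not twice.

# Numerical choices

Zero-phase 4th-order Butterworth filters applied forward-backward, with
odd-reflection padding because plain `filtfilt` start/end transients
otherwise distort short windows. Periodograms use a Hann window; band
energies partition (0, Nyquist] and satisfy Parseval to 1e-6 relative.
Variance floors: 1e-6 of pooled variance (activity), 1e-4 (OFF, whose
per-class samples are small). Ties: argmax ties broken by fixed class
order; wrapper-selection ties by schema order; ROC threshold ties toward
the lowest threshold. Sample SDs use the n-1 denominator; group comparisons
use Welch's t-test; report tables round half-up, and a metric below 1 is
displayed as at most 0.99 (an imperfect classifier is never printed as
perfect). Degenerate inputs: empty bins and no-movement bins carry explicit
`NA` no-data markers end to end; constant series make correlations `NA`;
an all-identical score vector makes the ROC degenerate and flagged as such.
Day-to-day repeatability reports both the squared Pearson correlation over
within-subject day pairs and the classical ICC(2,1) from the balanced
subject x day ANOVA, labeled separately, because published "ICC (r^2)"
columns are ambiguous between the two readings.

# Known limitations

Single-axis posture geometry (no magnetometer fusion); leg-tremor posterior
is whole-body rather than leg-specific (the per-ankle spectral scores
compensate); FoG detection requires trembling, so akinetic freezes are
missed by design; the dyskinesia severity scale is anchored on the synthetic
cohort, so absolute severities on other data need recalibration via
`tools/calibrate.R`; and all headline accuracies are synthetic-cohort
properties, as discussed above.
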