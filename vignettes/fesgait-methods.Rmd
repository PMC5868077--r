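---
title: "Adaptive FES for dropfoot gait: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive FES for dropfoot gait: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesgait)
```

## The control problem

Dropfoot — the inability to lift the forefoot during swing after a stroke —
is commonly treated with functional electrical stimulation (FES) of the
tibialis anterior (TA). Open-loop stimulators use a fixed intensity and a
fixed heel-off-to-heel-strike window, which over-stimulates some cycles,
under-stimulates others, and suppresses the plantar flexion push-off that
normally follows heel-off. `fesgait` implements a two-channel adaptive
scheme:

* **Intensity** (`u_out1`): a Mamdani fuzzy-logic controller updates the
  stimulation pulse amplitude once per gait cycle so that the maximum swing
  dorsiflexion $\theta_a$ tracks a healthy reference
  $\theta_{req} = 4.9^\circ$. Its inputs are the tracking error
  $e_k = \theta_{req} - \theta_a^{(k)}$ and its cycle-to-cycle change
  $\Delta e_k = e_k - e_{k-1}$; its output is a PWM duty ratio in $[0,1]$
  mapped to a pulse amplitude by `duty * amplitude_cap` and clamped to the
  0–120 mA stimulator range.
* **Timing** (`u_out2`): two linear models map the smoothed walking speed
  $n_s$ (mean of the last five step speeds, estimated from the toe marker)
  to the onset delay after heel-off, $417 - 112\,v$ ms, and the burst
  duration, $878 - 213\,v$ ms, so the burst lands on the physiological TA
  activation window at any treadmill speed.

Because no public recordings accompany this design, the package carries a
synthetic hemiparetic treadmill-walking plant, so the full closed loop and
the four study conditions — NS (no stimulation), HOS (fixed intensity,
heel-off to heel-strike), SAS (fixed intensity, speed-adaptive timing) and
IDAS (adaptive intensity and timing) — can be simulated, measured and
compared end to end.

## The fuzzy intensity controller

Both inputs use seven triangular membership sets (NB, NM, NES, ZE, PS, PM,
PB) on a symmetric universe, evenly spaced so memberships sum to one
everywhere (a Ruspini partition); out-of-universe values are clamped to the
nearest bound. The output uses three sets PS/PM/PB on the duty universe
$[0,1]$ with peaks 0.15/0.50/0.85 and flat shoulders at the edges, again a
Ruspini partition. Inference is standard Mamdani: rule strength
$\min(\mu_e, \mu_{\Delta e})$, per-label aggregation by max, clipping
implication, and centroid (centre-of-area) defuzzification by trapezoidal
quadrature on 1001 points (configurable; tested against a 10$\times$ finer
grid). If no rule fires — impossible with the default partitions, possible
with user-supplied ones — the previous duty is held.

Two design points deserve explanation:

* **Error sign.** The rule base awards its largest output to the
  (e = PB, Δe = PB) corner. That drives the loop toward the setpoint only
  if positive error means *insufficient* dorsiflexion, so the controller
  uses the corrective convention $e = \theta_{req} - \theta_a$.
* **Derivative universe.** The error universe defaults to
  $[-10, 10]^\circ$. The Δe universe defaults to $[-60, 60]^\circ$ — six
  times wider — which down-weights the derivative channel. This came out
  of closed-loop analysis: with per-cycle sampling, one intensity step can
  change $\theta_a$ by several degrees, so $\Delta e$ routinely spans the
  whole error universe. If the Δe sets are as narrow as the e sets, the
  rule rows for rising error (which output PB, duty 0.85) and falling
  error (PS, duty 0.18) dominate alternately and the loop settles into a
  large limit cycle instead of converging. Widening the Δe universe makes
  ordinary cycle-to-cycle fluctuations read as "Δe ≈ zero", leaving the
  proportional rows in charge, while abrupt changes still engage the
  derivative rows. Both universes are configurable.

A structural property of the rule base worth knowing: with
$\Delta e \approx 0$ the largest output is PM (duty 0.5), so a sustained
duty above 0.5 is not reachable at equilibrium. On a weak plant needing
more than half the amplitude cap the loop therefore settles at a residual
error rather than diverging — mirroring how tolerance-limited subjects
retain a residual dorsiflexion deficit.

## The speed-timing model

The two linear maps are evaluated in ms, clamped at zero (time cannot be
negative), and trusted on speeds in $[0.2, 2.0]$ m/s; outside that domain
the speed is clamped with a warning, since linear EMG-timing fits should
not be extrapolated. The stimulation window is
$[\text{heel-off} + \text{interval},\ \text{onset} + \text{duration})$,
truncated at the next heel-strike; if the onset itself falls past the next
heel-strike the cycle is skipped with a warning. The trigger trace
`u_out2` is 1 on samples in the half-open window.

## Signal processing

* **Joint angles** are computed in the sagittal (y–z) plane from the
  five-marker chain: knee = angle between thigh→knee and knee→ankle
  segments (0 at full extension, flexion positive); ankle = angle between
  the shank and ankle→toe segments offset so that shank ⊥ foot reads 0
  (dorsiflexion positive). A 2-D treatment is an assumption, not a claim
  about the original rig: treadmill gait is sagittal-dominant and all
  outcome metrics are sagittal.
* **Filtering** is a second-order zero-phase (forward–backward)
  Butterworth low-pass at 15 Hz, applied to cycle-complete data. Plain
  forward–backward filtering has visible end transients, so the series is
  padded by odd reflection at both ends (3 cutoff periods) before
  filtering; a constant series then passes through exactly.
* **Gait events**: heel-off and heel-strike are debounced footswitch
  transitions (transitions separated by <50 ms collapse to a single
  transition at the group's first edge). Toe-off, which a heel switch
  cannot sense, is kinematic: the first sample after heel-off where the
  toe marker rises 5 mm above its stance-phase median.
* **Step speed**: in the treadmill frame the planted foot tracks the belt,
  so the raw step speed is |toe-z displacement during stance| / stance
  duration, smoothed over the last five steps. Only the z (anterior–
  posterior) coordinate is used; using the full displacement vector would
  differ negligibly during stance and is not implemented.

## The synthetic plant

The plant emulates one hemiparetic treadmill walker:

* **Baseline trajectories** are smooth piecewise-cosine profiles keyed to
  phase fractions (heel-off at 40% of the cycle, toe-off at 62%), with an
  unstimulated swing dorsiflexion peak of 0.7°, plantar flexion at
  toe-off of −4.9° and a swing knee peak of 33° — a marked dropfoot
  pattern. Cycle duration is $1.4 - 0.3\,v$ s, snapped to the 100 Hz
  sample grid so multi-cycle recordings stay uniformly sampled.
* **Recruitment** is $r(A) = \tanh\!\big(((A - 5)/200)^{0.5}\big)$ for
  amplitudes above the 5 mA threshold: a monotone saturating curve with a
  brisk rise just above the motor threshold and a long gentle shoulder
  that does *not* saturate within the 0–120 mA stimulator range —
  clinically common for surface stimulation of a paretic TA, where
  tolerance ends well before full recruitment. The gentleness is a
  deliberate calibration: the per-cycle loop gain is the product of the
  controller's duty-per-degree slope and the plant's degrees-per-duty
  slope, and a recruitment curve steep anywhere in the operating band
  (roughly 20–60 mA) makes that product exceed one and the cycle map
  oscillate. The amplitude at any recruitment level is available via
  `recruitment_saturation()` (95% at ≈680 mA for the default subject).
* **Activation dynamics** are first order (rise 50 ms, decay 80 ms),
  integrated exactly per sample; the stimulation effect
  `max_added_dorsiflexion * a(t) * g(phase)` (default gain 12°) is gated
  by `g`, a cosine ramp over phase 0.55–0.65, confining it to late stance
  and swing.
* **Kinematics**: the marker chain is anchored at the toe — planted on the
  belt during stance (so stance toe-z displacement encodes the belt speed
  exactly) and following a smooth clearance path in swing whose initial
  rise is fast (`sin^0.7`), making kinematic toe-off detection land
  within one sample of ground truth. The thigh swings sinusoidally; the
  hip trajectory is emergent and oscillates vertically.
* **Noise** has two parts: a per-cycle angle offset (SD 0.2°,
  cycle-to-cycle variability, independent across cycles) and white
  measurement noise (SD 0.05°) on the angle traces. This split matters:
  the headline metric is a maximum over ~40 swing samples, and white noise
  of the full magnitude would bias that maximum upward by several tenths
  of a degree, whereas a per-cycle offset perturbs it unbiasedly.
* **Static response** `rest_angle + gain * r(A)` (seated resting angle
  −4°) supports the clinical intensity calibrations: HOS/SAS use the
  smallest amplitude reaching a neutral (0°) seated ankle; the IDAS cap is
  the tolerance cap unless "sufficient dorsiflexion"
  ($\theta_{req} + 2^\circ$) is reached statically at a smaller amplitude.

What the plant does **not** model: muscle fatigue, spasticity and
reflexes, EMG, frontal-plane eversion/inversion, double-support force
dynamics, marker soft-tissue artefact, and day-to-day electrode
variability. Closed-loop results on this plant therefore demonstrate the
controller's logic, stability and calibration machinery — not clinical
efficacy on patients, whose responses are less stationary than any fixed
recruitment curve.

## The experiment runner

`run_trial()` wires the loop per cycle: estimate the smoothed speed from
the *measured* toe marker (the first cycle uses the commanded belt speed,
which the operator set on the treadmill), build the condition's window,
deliver the stimulus, simulate, re-measure $\theta_a$ through the full
marker → angles → filter → events → metrics pipeline, and (IDAS only)
update the fuzzy controller. The intensity starts at zero, so the first
walking cycle is unstimulated and the first stimulated cycle uses the
first controller output; $\Delta e$ is zero on the first update.
Convergence time is measured from walking onset to the start of the first
cycle whose $|e| < 2^\circ$ with all later cycles also inside the bound.
An unreachable setpoint completes with non-convergence flagged (`NA`)
rather than an exception. `run_experiment()` crosses conditions × speeds
× seeds, and `summarize_trials()` reduces to condition-by-speed
mean ± SD tables of the three outcome metrics plus mean |e| and
convergence time.

## Numerical choices and degenerate inputs

* Defuzzification: trapezoid rule, 1001 points (≥101 enforced); tested
  against a 10,001-point oracle to 1e-4 duty units.
* Ties and edges: the output window is right-open; metrics use the sample
  nearest the toe-off event; a swing window with fewer than two samples
  drops the cycle with a warning; a non-finite $\theta_a$ skips the
  controller update and holds the intensity.
* Coincident markers (<1 mm segments), non-uniform sampling, missing
  columns and non-binary footswitch values raise named errors.
* Test problem sizes: closed-loop suites run 25–50 cycles per trial, with
  robustness checked across plant gains {6, 12, 20}°, all three speeds
  and three seeds — comfortably past the ~2 s settling transient while
  keeping the whole suite fast.

## Known limitations

* The rule-base transcription orientation (rows = Δe) and the corrective
  error sign are design decisions; the diagonal cells are
  orientation-invariant, and both the orientation and all membership
  parameters are configurable for users who want the alternative reading.
* At a weak plant gain (6°) the settled error hovers near 1.8° in the
  mean — the rule base cannot hold a duty above 0.5 at equilibrium — so
  individual noisy cycles can exceed the 2° envelope that the default
  subject satisfies per cycle.
* The speed-timing coefficients are fixed healthy-subject fits; per-subject
  re-fitting is out of scope.
* Marker I/O is CSV only; C3D/TRC binary formats are not parsed.
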