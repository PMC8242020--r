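---
title: "Simulating and analysing inter-brain coupling in joint cursor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing inter-brain coupling in joint cursor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When two people steer a single on-screen object together, does anything
happen between their brains beyond the fact that they are doing similar
things at similar times? dyadEEG implements the full computational chain of
a dyadic (hyperscanning) EEG study built around a *redundant joint
cursor-control* task: on every trial a pair of participants either each
control their own cursor (solo) or jointly control one shared cursor whose
velocity is the gated mean of their two thumb-stick inputs. The core
statistic is the sliding-window, lag-zero Pearson correlation between the
two participants' EEG series at each electrode — "inter-brain coupling" —
contrasted between joint and solo control against a label-shuffling
permutation null.

The package contains both the *analysis* chain (preprocessing, behavioural
kinematics, SSVEP and ERP measures, coupling maps, permutation and
single-trial statistics) and a *generator* (task engine plus closed-loop
dyad simulator with an EEG forward model), so that every stage is testable
end to end without any recorded data.

## The task engine

A session is a counterbalanced trial table: by default 15 blocks of 64
trials (960 total, 480 per control condition), fully crossing control
(solo/joint) × target-position pair (4) × tag-frequency assignment (17 or
19 Hz on the target) within each block, with seeded random presentation
order. Each trial runs rest (1000 ms), pre-cue placeholder (576 ms),
control cue (1424 ms, flickering at 7 Hz), a variable delay (500–1000 ms),
a 2500 ms action window after the spatial cue, and feedback (500 ms) —
6500–7000 ms in total.

The control law: a thumb stick reports per-axis displacement in [−1, 1].
Solo cursor velocity is the input × 7.5 px/frame at 144 frames/s when the
displacement magnitude √(x²+y²) exceeds the 10 % action gate, else exactly
zero. Joint velocity is the per-axis mean of the two inputs × 7.5, but only
when *both* actors exceed the gate. Pixels convert to degrees through a
single constant, 36.12 px/°, chosen so full deflection equals the stated
29.9 °/s maximum cursor speed (7.5 px × 144 Hz ÷ 36.12 px/° = 29.9 °/s).

Scoring mirrors the game logic: action onset is the first frame of nonzero
cursor velocity; a trial is correct when onset falls 200–800 ms after the
spatial cue, and the cursor's centre first enters and then remains inside
the 1°-radius target (at 8° eccentricity) for 200 ms within 1500 ms of
onset. Movement time (MT) runs from onset to that first qualifying entry
frame. Outcomes `too_fast`, `too_slow` and `missed` cover the remaining
cases exhaustively. On joint trials the two *invisible* solo cursors are
still computed and scored with the identical rules (and the invisible
joint cursor on solo trials), which is what separates real-time
coordination from mere input averaging.

## The dyad simulator

Each simulated actor is a proportional controller with a small set of
behaviourally meaningful parameters:

* `rt_mean_ms`, `rt_sd_ms` — lognormal action-onset latency (defaults
  420/60 ms for the higher-performing and 490/90 ms for the
  lower-performing actor);
* `motor_noise_sd` — per-frame Gaussian heading noise (10° / 22°);
* `gain` — deflection per degree of distance-to-goal (1.2 / 1.0);
* `aim_noise_sd` — per-attempt aiming error in degrees (0.9 / 1.15): the
  actor steers toward a Gaussian-perturbed aim point and re-aims every
  `aim_interval_ms` (500 ms) while the cursor it can see sits outside the
  target. Misses and the late, variable action offsets of error trials
  emerge from this, not from a scripted error rate;
* `joint_rt_slowing` (1.12) and `joint_slowing` (2.4) — on joint-control
  trials, onset latency is ~12 % slower (shared control demonstrably slows
  initiation moderately in this task family) and corrective re-aims come
  ~2.4× more slowly, every ~1.2 s (coordinating corrections through a
  shared cursor is the expensive part; without this cost the averaging of
  two aim errors makes the joint cursor implausibly accurate);
* `giveup_sd` (0.25) — actors know the 1500 ms completion deadline and, on
  failed trials, disengage around it at `onset + 1500·(1 + N(0, 0.25))`.
  Disengagement timing is individual, so error trials end with misaligned
  offsets between co-actors, as human error trials do.

With these defaults the solo visible accuracies of the two actors bracket
roughly 65–85 % and joint visible accuracy lands near 75–80 %, with
invisible-cursor accuracy an order of magnitude lower — the qualitative
regime of the human task. The release policy (let go of the stick once the
seen cursor has dwelled 200 ms in the target) is what couples the two
actors' action offsets under shared control: both release off the same
event, so across-trial offset correlations approach 1 under
`closed_loop_shared` and vanish under `independent`. We make no claim that
the simulator reproduces human means; it reproduces orderings and
mechanisms, and the tests only assert those.

Gaze is generated as fixation jitter, a saccade tied to the actor's action
onset with a −150 ms lead (gaze reaches the target before the cursor, as
human gaze does), Gaussian landing error, Poisson blinks that zero the
pupil, and pupil noise, at the 120 Hz tracker rate.

### The EEG forward model

Synthetic EEG is an explicitly additive sum over a 61-channel 10-10
montage (CPz is the reference and carries no signal):

* 1/f background (exponent 1, 10 µV per channel), part independent per
  channel, part shared across channels as a volume-conduction stand-in;
* a 7 Hz control-cue SSVEP (2 µV, occipital Gaussian gain map centred on
  Oz, phase-locked to cue onset) with a ×1.15 amplitude modulation on
  joint trials — a synthetic effect size chosen for power tests, not an
  empirical value;
* 17/19 Hz target/distractor tags (0.75 / 0.10 µV, occipital), phases
  aligned to the spatial cue;
* small biphasic visual onset potentials to the fixation, control and
  spatial cues (occipital);
* the action-offset potential: a slow central (Cz-centred) waveform with
  peaks near 200, 500 and 800 ms after offset and alternating polarity,
  max-normalised and scaled to 6 µV. Its spectral energy sits below 4 Hz
  (delta band) by construction, which the tests verify through the Morlet
  transform rather than assume.

The offset potential is generated by each participant's *own* action: it
is inserted at that participant's own controller offset in both
conditions. The condition difference is carried entirely by offset
*alignment*, which is the studied mechanism: under shared control both
actors release off the same dwell event, so their offsets — and hence
their offset ERPs — coincide on successful joint trials; under solo
control (and on failed joint trials, where each actor disengages near the
completion deadline at an individually variable time) the offsets drift
apart and the ERPs no longer overlap within the trial. An offset-locked
component therefore produces late within-trial inter-brain correlation on
correct joint trials only. Because the noise stream is seeded
separately from the deterministic components, a synthesis restricted to
one component reproduces exactly its share of the full mix
(`include = "noise"` etc.), and the additivity is asserted in the tests.

The synthesis rate is a configuration field. Acquisition-grade recordings
would use 2000 Hz; the packaged analyses synthesise at 256 Hz — already
the SSVEP analysis rate, and comfortably above twice the highest component
(19 Hz tag; 45 Hz low-pass edge) — and the test fixtures at 128 Hz. What
the generator does *not* emulate: biophysical head geometry, artefacts
(blinks, muscle, line noise), non-stationary background statistics,
learning across trials. Passing tests therefore show the *pipeline*
recovers what the forward model encodes; they cannot certify performance
on real recordings.

## Preprocessing

Filtering applies 4th-order Butterworth responses at zero phase: high-pass
0.5 Hz, low-pass 45 Hz, notch as a 49–51 Hz band-stop. The default
implementation multiplies the reflection-padded spectrum by the squared
Butterworth magnitude response — the amplitude response of a
forward-backward (`filtfilt`) pass, applied to all channels in one
transform; the classic per-channel recursion is available as
`method = "filtfilt"` and the two agree in the passband to 1 %. Epochs are
cut around named markers; trials whose within-epoch peak-to-peak range
exceeds 100 µV on any channel are flagged invalid (an absolute-value
variant sits behind a switch), and flagged trials are carried, never
dropped. Resampling targets 256 Hz for SSVEP analyses and 64 Hz for
correlational analyses: an exact (brick-wall) spectral anti-alias filter
at the target Nyquist followed by spline interpolation onto the new grid,
so in-band amplitudes are preserved essentially exactly; marker indices
are remapped proportionally. Gaze cleaning masks ±200 ms around blinks (runs
of ≥3 invalid/zero-pupil samples) and samples whose pupil-area first
difference exceeds the recording's 99.99th percentile; masked samples stay
masked — no interpolation. The stage order is filter → epoch → reject →
resample. Eye-movement topographic interpolation from the original
acquisition chain is proprietary and out of scope.

## Behavioural and coupling measures

Controller displacement is 100·√(x²+y²) percent; onsets/offsets are the
first/last frames above the 10 % gate. Trajectory curvature is the Menger
(three-point circle-fit) curvature: at each interior frame, the inverse
circumradius of the circle through the frame and its neighbours,
`k = 4·Area/(|ab||bc||ac|)`, decomposed into signed x/y components along
the normal toward the circumcentre. Stationary (repeated-point) triples
are degenerate and excluded from the trial mean; collinear triples have
k = 0; the tests pin the implementation to exact circle and circumradius
solutions and to translation/rotation invariance at 1e-9. Endpoint
displacement is the final-frame distance to the target centre. HP/LP
(higher-/lower-performing) sorting happens either at experiment level
(per metric, over visible solo trials, ties to the lower participant
index) or per trial (sorting the two solo values, used for continuous
kinematic metrics).

Interpersonal behavioural measures are all zero-lag: within-trial Pearson
correlation of the two displacement series (full action window by
default, including pre-onset zeros; a movement-only switch exists because
the original analysis window is not fully specified), across-trial
correlations of onset/offset times (pairwise-complete, ≥3 pairs),
maximum inter-cursor distance, inter-gaze distance over pre-action
(−2.5–0 s) and action (0–2.5 s) epochs on jointly valid samples (missing
below 10 % joint validity), and gaze/cursor distance-to-target profiles
on 0–100 % normalised movement time. Zero-variance series yield missing
values with a recorded reason, never a fabricated 0.

## Neural measures

ERPs are arithmetic means over valid trials. Amplitude spectra use the
single-sided 2/N FFT convention, so a sinusoid of amplitude A occupying an
integer number of window cycles reads out as A at its bin; the control-cue
epoch is the full 1424 ms cue period and the target/distractor window is
0–2 s after the action cue, both at 256 Hz. Harmonics are computed but
never summed into the fundamental. The Morlet transform follows the
central-frequency/FWHM convention (defaults 1 Hz and 3 s; envelope SD
scales inversely with frequency), normalised so a sinusoid of amplitude A
gives ridge amplitude A; edge samples where the ±3 SD support leaves the
epoch are flagged. Offset-locked ERPs cut −0.5 to +1 s around per-trial
offsets, with the same per-condition time-locking rule as the forward
model (own offsets for solo, the common joint-cursor offset for joint).

## Inter-brain coupling and inference

For every trial, electrode and window position, the Pearson correlation is
computed between the two participants' same-electrode segments — within
trial first, then averaged across trials, because the per-trial values
feed the single-trial statistics. The window is 500 ms long and slides in
one-sample steps at the 64 Hz analysis rate (15.6 ms); step size is
configurable. Windows are centred on their reported timepoint; edge
windows truncated below half the window length are dropped, the rest are
flagged and excluded from inference. A trial invalid for either
participant is excluded for both, and zero-variance cells become missing
rather than zero.

The joint-minus-solo contrast is thresholded by a pooled-datapoint
permutation null: trial labels are shuffled *within* each pair (keeping
the two participants' simultaneity, breaking only the condition
assignment), the grand-mean contrast is recomputed across pairs, and all
electrode × time datapoints of all permutations pool into one null
distribution whose α/2 and 1−α/2 quantiles (α = 1e-4 two-tailed) gate the
observed map. A max-statistic variant is available as the stricter
alternative. Monte-Carlo p-values use (1+k)/(1+B); exhaustive enumeration
is used when requested and feasible, and the two agree on toy problems by
construction of the tests. The peak spatiotemporal slice is the largest
significant contrast cell, ties resolved first by earlier time then by
montage order.

Single-trial statistics at the peak slice: per pair and condition, Pearson
correlations between per-trial coupling and each behavioural metric, with
paired and one-sample t-tests at group level; and per-pair standardised
OLS regressions of coupling on z-scored predictors, betas averaged across
pairs, tested one-sample with Bonferroni familywise control (α/k, 0.0125
for four predictors), unique variance reported as mean squared
semi-partial correlation. Repeated-measures ANOVAs delegate to `aov` with
subject error strata; partial eta squared is SS_effect/(SS_effect +
SS_error-of-stratum).

## Numerical and design choices

* FFT bin read-out takes the nearest bin; analysis windows are chosen to
  hold integer cycles of the tag frequencies so no leakage correction is
  needed.
* 1/f noise is generated by spectral shaping with the DC bin zeroed
  (zero-mean output) on a padded, highly composite FFT length.
* The "1.56 ms increment" of the original sliding-window description
  equals one sample at 640 Hz, but the correlational analyses ran at
  64 Hz; we read it as one sample at the analysis rate (15.6 ms) and
  expose the step as configuration.
* Permutation defaults: 1000 reshuffles for coupling grids, more for
  scalar contrasts when cheap; counts are configuration, not doctrine.
* Degenerate inputs (zero-variance series, constant pupil, single-pair
  t-tests) produce missing values with reasons instead of errors wherever
  a partial result is scientifically meaningful.
* The fitted pixel/degree constant, target geometry, response windows and
  all rates sit in `task_constants()` / `pipeline_config()` rather than
  in function bodies.

## Problem sizes

The packaged end-to-end demonstration (`run_pipeline()`) and the
acceptance script simulate 20 pairs × 48 trials (3 blocks of 16) with EEG
synthesised at 256 Hz and coupling analysed at 64 Hz, with 1000
permutations — the number of pairs matches the study design this pipeline
serves; each block holds every factorial cell once, and 24 joint trials
per pair yield enough error trials (roughly one in five) for the
within-pair correct-versus-error coupling contrast. Module tests run on
smaller fixtures (16 trials, 128 Hz). Full-scale sessions (15 × 64
trials, 2000 Hz) run through the identical code paths by changing the
configuration.

## Known limitations

* The actor model is a deliberate stand-in: proportional control with
  aim-and-correct attempts. It reproduces orderings (visible ≫ invisible,
  shared-mode coupling > independent, gaze leads cursor), not human means,
  and simulator outputs should never be quoted as reproducing human
  values.
* The forward model is linear and stationary; artefact handling is
  exercised only through synthetic amplitude excursions.
* EDF import is not provided; BrainVision (binary float32 or ASCII) is the
  exchange format, and array artefacts persist to RDS rather than HDF5.
* Inter-brain coupling is Pearson-only by design — no phase-locking,
  coherence or directed measures.
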