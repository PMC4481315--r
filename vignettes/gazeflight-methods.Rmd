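---
title: "Methods: gaze, wingbeat and landing-cue analysis for maneuvering bird flight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze, wingbeat and landing-cue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeflight)
```

## The problem

Small parrots performing a U-turn in a confined arena reorient their gaze
almost entirely with rapid head saccades: the head snaps through tens of
degrees in tens of milliseconds, is held rotationally stable in between,
and the body follows with a slower, continuous rotation. The analysis
questions are kinematic: when do saccades happen relative to the wingbeat,
how much of the reorientation do they carry, which arena features are
stabilized in the frontal visual field between saccades, and which optical
variable most plausibly triggers the landing on a swinging perch.

`gazeflight` implements this pipeline over per-trial marker time series
(two head markers at full rate, shoulders and wingtips at four instants
per wingbeat), together with a synthetic trial generator that produces the
same data with known ground truth so that every stage has a
parameter-recovery test.

## Coordinate conventions

The arena planform is 0.6 m x 1.0 m with the 0.213 m perch near one end
(0.115 m from a side wall). x runs along the long axis, y across the
width; yaw 0 deg faces +x (away from the perch), 180 deg faces the perch,
positive yaw is a leftward (counter-clockwise, toward +y) rotation. All
angles are degrees, time seconds, positions meters. Azimuths of arena
features relative to head yaw are positive in the left visual hemisphere.

## Smoothing

Coordinate and yaw channels are smoothed with a discrete penalized
least-squares (Whittaker) smoother: minimize
`sum(w_i (y_i - z_i)^2) + lambda * sum((second difference of z)^2)`.
Gaps get weight 0, so sparse wingbeat-rate channels are smoothed and
interpolated to the full rate in one pass. Penalties are fixed, not
optimized: lambda = 100 for coordinates, 5000 for head yaw, 1e6 for body
yaw, chosen conservatively so the leave-one-out cross-validation error
(cve) stays below 0.5 signal units, 1 deg and 2 deg respectively on data
with realistic tracking noise. The difference order is 2, the standard
choice that makes the smoother behave like a Savitzky-Golay filter.

Numerical choices worth recording:

* Yaw is unwrapped (cumulative, no +/-180 jumps) before smoothing; a
  U-turn sweeps more than 180 deg and smoothing wrapped angles corrupts
  derivatives.
* cve is the root-mean-square leave-one-out residual, computed exactly
  through the smoother's hat-matrix diagonal. At lambda = 0 the hat
  diagonal is 1 and the identity degenerates, so the cve is taken in the
  lambda -> 0+ limit, where the deleted point is predicted by
  minimum-roughness interpolation through its neighbours (for interior
  points `z_i = (-y_{i-2} + 4 y_{i-1} + 4 y_{i+1} - y_{i+2}) / 6`).
* Derivatives are central differences (one-sided at the ends), length
  preserving.

## Saccade detection

A saccade is a maximal run of samples with |omega| strictly above
400 deg/s lasting at least 12 ms (24 samples at 2000 Hz). Two
supra-threshold runs separated by any sub-threshold gap are distinct
events. For amplitude, boundaries are extended outward from each
threshold crossing to the nearest sample where |omega| drops below
100 deg/s or reaches a local minimum, whichever comes first within 10 ms.

Two measurement details follow from the smoother's impulse response:

* **Amplitudes are read from the raw yaw trace.** The smoothed trace
  rings around each saccade (about 2% overshoot per side at lambda =
  5000 for a 25 ms saccade), so single-sample boundary values on it are
  biased. Instead the amplitude is the difference of the mean *raw* yaw
  over the stabilized plateaus flanking the extended boundaries (up to
  20 ms per side, clipped at neighbouring events). Noise-free this is
  exact; with 1.3 mm marker noise the plateau average suppresses the
  ~3.8 deg per-sample yaw noise to a few percent of a typical amplitude.
  Because the residual error is Gaussian, the 10% recovery property is
  asserted on the error distribution (>= 90% of events within 10%,
  median below 5%), not on every single event.
* **Stroke-phase histograms use the threshold crossings.** Smoothing
  spreads the velocity bump symmetrically, so any onset-of-velocity
  reading is early by about the kernel half-width (~5 ms); the 400 deg/s
  crossing, by contrast, slides down the attenuated rising flank and
  lands within ~1 ms of the true onset. Both boundary sets are reported
  on every event.

Saccade summary statistics aggregate flight -> bird -> cohort, never
pooling raw events across birds. The amplitude-duration regression is
ordinary least squares of amplitude (deg) on duration (ms), slope
reported in deg/s.

## Turn segmentation

The U-turn is segmented from the planform wingtip positions at
mid-downstroke: the heading of the segment between consecutive mid-stroke
positions is compared with the pre-turn running heading (circular mean of
the first three segments). The turn starts at the first beat whose
outgoing segment deviates by more than 20 deg and ends at the first beat
whose successive segment headings re-align within 20 deg. The 20 deg
threshold separates straight-phase wobble from turn-phase curvature on
synthetic traces and is configurable; disjoint deflection episodes are
counted, and more than one flags a violation of the single-U-turn
inclusion criterion. The implementable flight filters are the single
U-turn, an altitude change (max minus min head height) below 0.21 m and a
take-off heading within 45 deg of the initial flight direction;
camera-coverage, first-landing-attempt and mesh-occlusion criteria are
video-level and out of scope.

## Wingbeat modes

Instantaneous flap frequency (1 / beat period) and downstroke/upstroke
period ratio are fitted with a two-component Gaussian mixture
`f(x) = xi1 N(mu1, sigma1) + xi2 N(mu2, sigma2)` by EM. Initialization is
deterministic (means at the 25th/75th percentiles, equal weights, common
SD), a variance floor of `1e-6 var(x)` prevents component collapse, the
log-likelihood is asserted non-decreasing, and convergence uses a
relative tolerance (unimodal samples converge slowly in absolute terms).
A fit counts as bimodal iff `|mu1 - mu2| > 2 max(sigma1, sigma2)` and
`min(xi1, xi2) > 0.1`. Beats are classified by the frequency separator
(midpoint of the component means; for a cohort, the mean of per-bird
midpoints), with frequency at or above the separator labeled normal -- a
beat gets one label, so the ratio separator is reported but not used for
labeling. Phase-usage percentages are computed per bird (missing cells as
zero) and then averaged.

## Gaze features

Feature azimuths are signed planform angles from the head-yaw heading to
the head-to-feature vector; perch features use the tracked swinging-perch
position when available, else the rest position. At wingbeat-rate
resolution, intersaccadic samples are selected by excluding whole beats
whose within-beat yaw SD exceeds 10 deg. Histograms use left-closed
10-deg bins on [-90, 90); azimuths outside that range are kept in the
series but not binned. Each feature's counts are normalized by the summed
counts across all features of the same bird -- we read the stated
normalization ("divide each distribution by the cumulative sum of all
other feature distributions") as sharing one unit of probability mass per
bird across features, which makes peak heights comparable between
features; per-bird histograms are then averaged. The +/-10 deg
feasible-eye-motion band is annotation only, never a filter.

## Landing cues

For trials with a landing-initiation annotation (tail-pitch instant),
alpha is the azimuthal extent of the perch (difference of the edge
azimuths), Omega = d(alpha)/dt with alpha smoothed at the coordinate
grade (lambda = 100) before differentiation, RREV = Omega / alpha and
tau = alpha / Omega (tau masked where Omega ~ 0; tau * RREV = 1 wherever
both are defined). Flight speed is the planform head-position derivative;
relative speed is the magnitude of the velocity relative to the perch
center. The c.v. analysis divides the SD across trials by the mean across
trials at each step of a common time grid from -85 ms to landing
initiation, pooling trials (a per-bird option exists); the -30..0 ms
visuomotor band is annotated, not excluded. The winner is the parameter
with the lowest window-mean c.v. The downsampling check decimates alpha
before any derivative and reports the Spearman rank correlation of the
parameter ordering against the full-rate analysis.

## The synthetic generator

The generator emulates the study conditions: 2000 Hz sampling, a
0.6 x 1.0 m arena, a 1.15 s U-turn flight with straight/turn/straight
speeds near 1.05 / 0.51 / 1.03 m/s, two wingbeat modes (intermittent
9.5 Hz with down/up ratio 0.53, normal 17 Hz with ratio 1.35, intermittent
weight 0.25), saccades launched at 75% of the downstroke inside the turn,
a swinging perch (fore-aft amplitude 0.10 m, sideways 0.01 m) and i.i.d.
Gaussian marker noise of 1.3 mm. Values not stated anywhere were chosen
once on realism grounds and left alone: perch swing period 1.2 s (a
pendulum of plausible length), head marker separation 28 mm (which makes
1.3 mm positional noise produce the reported ~3.8 deg yaw orientation
error), shoulder separation 50 mm, wing length 0.135 m, stroke amplitude
1.9 rad (which reproduces advance ratios near 0.12 straight / 0.06
turning at the configured speeds).

Design choices where the construction was genuinely open:

* **Saccade waveform.** Each saccade is a raised-cosine velocity bump
  (zero velocity and acceleration at its endpoints), giving the analytic
  relation amplitude = peak x duration / 2 that the recovery tests use.
  Any smooth unimodal profile would do; the tests rely only on the
  generator's own analytic truth.
* **Head = drift + saccades.** Head yaw is `drift_gain x body profile +
  sum of saccade steps`, with the drift gain solved so head and body end
  the turn aligned. This makes the smooth "body-carried" drift supply
  exactly the reorientation the saccades do not, keeps intersaccadic
  head velocity near 130-160 deg/s (below the 400 deg/s threshold), and
  reproduces the qualitative head-body interplay of real turns.
  Detector-calibration trials set `drift_gain = 0` to isolate saccades
  on a stationary base.
* **Body turn profile.** A smooth trapezoid (cosine ramps over 10% of
  the window at each end, constant-rate plateau) rather than a single
  raised cosine: the body rotation of a real turn is steady, and the
  crisp onset gives the wingtip trace the characteristic deflection used
  for segmentation.
* **Landing trigger.** The tail-pitch annotation is emitted by the
  generator, optionally as the first frame where alpha crosses a
  configured threshold; this builds cohorts in which alpha is the true
  trigger, the recovery target of the c.v. analysis.

What the generator does **not** emulate: aerodynamics, wing occlusion of
the visual field, eye-in-head movement, manual-tracking dropouts, and any
correlation structure in the tracking noise. Passing tests therefore show
that the pipeline recovers known kinematic ground truth under realistic
noise and sampling, not that it would be robust to every artifact of real
video tracking.

## Problem sizes

The test suite and the analysis scripts run 16-trial U-turn cohorts
(about 240 wingbeats and 90 saccades) and 12-trial landing cohorts at the
full 2000 Hz rate, with 1000 random traces for the detector/oracle
equivalence check -- sizes chosen to exercise every code path while a
full run of the suite stays under a minute.

## Known limitations

* The boundary-extension floor (100 deg/s) sits below the intersaccadic
  drift of fast turns, so extended onsets inherit the smoothing kernel's
  ~5 ms spread; use the threshold crossings when timing matters.
* c.v. is undefined where the across-trial mean is near zero (Omega
  around a perch-swing reversal); those steps are masked, which can
  shrink the effective window for derivative-based parameters.
* The EM fit is 1-D and two-component by design; no model selection is
  attempted.
* Body yaw rests on sparse shoulder samples; with fewer than about three
  samples per wingbeat the interpolated body trace and everything
  derived from it (relative amplitudes, relative velocities) degrades.
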