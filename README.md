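# gazeflight

Analysis pipeline for the gaze and flight kinematics of small birds
performing rapid U-turn maneuvers. Lovebird-style "turn on a dime"
flights combine three tightly coordinated behaviors: super-fast head
saccades (peak yaw velocities beyond 2000 deg/s) that carry most of the
gaze reorientation, an intermittent wingbeat that alternates two flapping
modes, and frontal stabilization of salient arena features between
saccades — culminating in a landing on a swinging perch that appears to
be triggered by the retinal size of the perch. `gazeflight` turns
per-trial 3-D marker recordings (head markers at 2000 Hz, shoulders and
wingtips at four instants per wingbeat) into the corresponding
statistics, and ships a synthetic trial generator with known ground truth
so that every stage is testable by parameter recovery.

The core quantities:

* **Whittaker smoothing.** Channels minimize
  `sum(w_i (y_i - z_i)^2) + lambda * sum((Delta^2 z)^2)` with gap weights
  zero (sparse channels are interpolated to full rate in the same pass);
  leave-one-out cross-validation error is computed exactly from the hat
  diagonal. Defaults: lambda 100 (coordinates), 5000 (head yaw),
  1e6 (body yaw).
* **Head saccades.** Yaw Phi is the planform arctangent of the head
  marker pair (0 deg = away from the perch, positive = leftward);
  omega = dPhi/dt. A saccade is |omega| > 400 deg/s sustained >= 12 ms,
  with amplitude read between boundaries extended to a 100 deg/s floor.
  Per-saccade statistics aggregate flight -> bird -> cohort, and
  amplitude (deg) regressed on duration (ms) estimates the preferred
  saccadic head speed.
* **Wingbeat modes.** Flap frequency and downstroke/upstroke ratio are
  fitted per Eq. `f(x) = xi1 N(mu1, sigma1) + xi2 N(mu2, sigma2)` by EM;
  a fit is bimodal iff `|mu1 - mu2| > 2 max(sigma1, sigma2)` and
  `min(xi1, xi2) > 0.1`; beats below the frequency separator are
  intermittent. The advance ratio per beat is `J = V / (2 A f R)`.
* **Gaze features.** Azimuths of wall corners, the gray wall panel and
  the perch relative to head yaw, restricted to intersaccadic samples
  (at wingbeat rate: beats with within-beat yaw SD > 10 deg are
  excluded), binned in 10-deg bins over [-90, 90) and normalized so each
  bird's features share one unit of probability mass.
* **Landing cues.** alpha = azimuthal extent of the perch,
  Omega = d(alpha)/dt, RREV = Omega/alpha, tau = alpha/Omega, plus
  absolute and perch-relative flight speed, aligned at the tail-pitch
  landing initiation. The coefficient of variation (SD/mean across
  trials per time step, -85..0 ms) ranks the parameters; the lowest c.v.
  marks the most parsimonious landing trigger.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
synthetic cohorts and write tables under `results/`. For example:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_saccades.R
Rscript analysis/03_wingbeat_modes.R
Rscript analysis/05_landing_cues.R
```

prints (abridged):

```
Simulated 16 U-turn flights (254 wingbeats, 92 injected saccades) ...
Detected 92 saccades in 16 flights.
Cohort medians: amplitude 29.6 deg, duration 24.7 ms, peak 1557 deg/s.
Amplitude-duration regression: slope 1821 deg/s, intercept -15.2 deg, R^2 0.80.
Frequency mixture: 9.56 / 16.93 Hz (separator 13.24 Hz), bimodal: TRUE.
Published cross-bird summary: normal 17.01 +/- 0.87 Hz, intermittent 9.58 +/- 0.48 Hz, separator 13.3 Hz.
Window-mean c.v. per optical parameter (-85..0 ms):
    alpha omega_exp      rrev       tau speed_abs speed_rel
   0.0262    0.2837    0.3023    0.4363    0.1859    0.3223
Most parsimonious landing cue: alpha.
After 2000 -> 50 Hz downsampling the winner is alpha (rank correlation 1.00).
```

The mixture means recover the generator's 9.5 / 17 Hz modes; the
cross-bird summary of the published per-bird mixture parameters
(`inst/extdata/wingbeat_gmm_published.csv`) reproduces the cohort
wingbeat numbers; and the landing analysis identifies the perch's retinal
size (alpha) as the least variable — hence most parsimonious — landing
cue, robustly across acquisition rates.

A minimal interactive session:

```r
library(gazeflight)
tr  <- generate_trial(synth_config(seed = 1))
yaw <- compute_yaw(tr$rec)               # smoothed head/body yaw, omega, speed
ev  <- detect_saccades(yaw)              # one row per saccade
seg <- segment_turn(tr$rec)              # before / during / after turn
saccadic_fraction(yaw, ev, c(seg$t_turn_start, seg$t_turn_end))$percent
```

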