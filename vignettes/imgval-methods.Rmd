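---
title: "Validating instrumented-mouthguard head-impact detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating instrumented-mouthguard head-impact detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgval)
```

## The problem

Instrumented mouthguards (IMGs) measure head kinematics during collision
sport: triaxial accelerometers and a gyroscope embedded in a custom-fitted
mouthguard record the linear and rotational acceleration of the skull through
rigid coupling to the upper dentition. Before exposure statistics from such a
device can be trusted, its event detection must be validated against an
independent standard — typically frame-by-frame video coding of every contact
event a player is involved in. The validation question is diagnostic: of the
direct head impacts a reviewer can verify on video, how many did the device
capture (sensitivity), and of the device's captures, how many correspond to a
real direct head impact (positive predictive value, PPV)?

`imgval` implements that study design end to end as testable code. Because
raw recordings from proprietary devices are not generally available, the
package pairs the analysis pipeline with a synthetic-data generator that
emulates the essential statistical structure of an elite rugby union season:
event rates per athlete exposure, skewed impact-magnitude laws, handling
artifacts, vocalization noise, and an imperfect video log with unclear
(obstructed) events. Every downstream stage can therefore be exercised, and
its parameter recovery quantified, without any external data.

## The device model

The simulated device mirrors a contemporary IMG:

* three triaxial accelerometers sampling at approximately 3,200 Hz
  (200 g full scale), each with an independent rate offset of up to
  ±1% to force the resampling stage to do real work;
* one triaxial gyroscope at approximately 800 Hz;
* an event trigger at 10 g on the absolute value of a single accelerometer
  axis, with a capture window of 20 ms before to 80 ms after the trigger and
  an 80 ms extension for every re-trigger inside an open window, so that
  multi-peak loading from one impact is captured as one event;
* capture processing: all streams linearly interpolated onto a uniform
  3,200 Hz grid, zero-phase 4th-order 300 Hz low-pass Butterworth filtering,
  rigid-body transformation of each accelerometer to the head centre of
  gravity, and fusion of the three estimates by their sample-wise mean;
* an inclusion rule discarding events whose centre-of-gravity peak linear
  acceleration (PLA) stays below 10 g, and a noise screen discarding events
  whose 300 Hz-filtered trigger-sensor resultant never reaches that
  threshold (the signature of vocalization and other high-frequency noise).

Peak linear acceleration (PLA, g) and peak rotational acceleration
(PRA, rad/s²) are defined as the maxima of the resultant (Euclidean-norm)
time series over the capture window.

### Rigid-body transform

With `r` the accelerometer's position relative to the head centre of gravity
(head anatomical frame: x anterior, y left, z superior) and `R` the
mouthguard-to-head rotation, the inverse model applied by the pipeline is

    a_cg = R a_sensor − α × r − ω × (ω × r)

where `ω` is the gyroscope angular velocity and `α` its time derivative,
computed by five-point central finite differences (exact for polynomials up
to degree four, one-sided stencils at the ends). The generator applies the
matching forward model per sensor, so the transform is genuinely inverted,
not bypassed. The default geometry places the three sensors on a 60 mm
dental arch roughly 80 mm anterior-inferior of the centre of gravity; with
season-typical PRA the rotational terms contribute of order 10 g at the
sensor positions, so skipping the transform would visibly corrupt recovered
magnitudes.

### Numerical choices

* Resampling is linear interpolation with endpoint preservation; at the
  native rates the worst-case amplitude loss for a 10 ms haversine pulse is
  a few tenths of a percent.
* The Butterworth filter is designed by `signal::butter`; the zero-phase
  application runs the causal filter forward and backward with constant
  end-padding (padding trimmed from the result). A single causal pass
  attenuates a tone at the cutoff by −3 dB exactly; the zero-phase pass
  squares the magnitude response and leaves symmetric pulse peaks at their
  sample of origin.
* Capture windows are half-open `[start, end)` on the uniform grid; windows
  are kept disjoint by clipping a window that would open inside its
  predecessor's tail at the predecessor's close.
* Samples at or beyond 200 g are flagged as saturated, never repaired.

## The synthetic season

One `session_config()` describes one athlete exposure. Defaults are the
season-level study conditions, condensed in time:

| Parameter | Default | Basis |
|---|---|---|
| contact events per exposure | 11 direct head impacts + 22 headless contacts | ~2,018 contacts and ~700 video-identified direct head impacts over 61 exposures |
| impact PLA law | median 21.5 g, IQR 15.4–33.9 | season magnitudes of verified head impacts |
| impact PRA law | median 1,702, IQR 1,170–2,772 rad/s² | season magnitudes |
| handling artifacts | Poisson, 54/61 per exposure; PLA median 62.6 g (24.6–106.7); 43/54 during ball-out-of-play | season false-positive mix |
| vocalization bursts | Poisson, 2 per exposure | chosen as a plausible nuisance rate |
| unclear coding probability | 257/2018 | season unclear fraction |
| video miss probability | 0.005 | small reviewer error rate |
| video timestamp jitter | ±0.5 s uniform | exercises matching tolerance |
| baseline noise | 0.3 g RMS per axis | below trigger threshold; devices are quiet at rest |
| pulse durations | uniform 8–16 ms | typical direct-impact pulse widths |
| session length | 60 s | see below |

A session is **condensed**: per-exposure event counts are season-realistic,
but the quiet time between events is compressed into 60 s so that a full
61-exposure season simulates in ~20 s and a 50-replicate recovery experiment
stays affordable. Events are placed in jittered slots, so neighbouring
capture windows never overlap and the ±2 s matching tolerance still operates
in a regime where cross-matching errors are rare, as in real (much sparser)
game time. Impact times are snapped to the nominal accelerometer grid so
that injected peaks land on samples.

### Magnitude law

Field studies report skewed magnitudes as median and IQR, and the reported
quartiles are asymmetric on the log scale (21.5/15.4 vs 33.9/21.5). A
log-normal with a single log-scale cannot reproduce both quartiles — it
misses each by about 6%. `sample_magnitude()` therefore uses a **two-piece
log-normal**: `X = median · exp(σ_lo Z)` for `Z < 0` and
`median · exp(σ_hi Z)` for `Z ≥ 0`, with each log-scale solved from its own
quartile (`σ = log(q/median)/Φ⁻¹(0.75)`). Median and both quartiles are then
exact in distribution, and the shape remains log-normal-like in each tail.

### Detection sensitivity as a generator knob

Each direct head impact carries a Bernoulli miss indicator
(`sensor_miss_prob`): missed impacts draw their PLA from the magnitude law
conditioned below the 10 g capture threshold, captured impacts at or above
it. Under the season's PLA law the sub-threshold mass is ~6%, close to the
default miss probability, so the unconditional law is essentially undistorted.

The capture chain itself additionally loses a small fraction of *capturable*
impacts — near-threshold events whose single-axis trigger never fires
(the trigger sees the sensor-frame signal, whose largest axis component can
stay below 10 g even when the resultant exceeds it) or whose measured CG PLA
lands fractionally below the inclusion threshold. A seeded 700-session
calibration run of the default generator and pipeline put this loss at
1.1% (`CAPTURE_CHAIN_LOSS`). `tuned_miss_prob(s)` converts a target
end-to-end detection sensitivity into the miss knob,
`1 − s/(1 − 0.011)`; the package default emulates the observed season value
655/700 ≈ 0.936.

### Artifacts and vocalization

Handling artifacts (mouthguard removal and adjustment) are driven through
the same rigid-body forward model as impacts — the handled mouthguard moves
as one body — so the pipeline measures their magnitude law faithfully, plus
a 500 Hz burst at 40% of peak that makes them broadband; they survive the
300 Hz filter and become false-positive captures, most of them during
ball-out-of-play periods. Vocalization bursts concentrate their energy at
600 Hz with ~1 g of low-frequency content: they exceed the raw trigger
threshold but fall below 10 g after filtering and are discarded by the noise
screen. Neither produces a video event; false positives are attributed to
ball-out-of-play handling by looking up the nearest ground-truth event, the
simulated analogue of reviewers re-examining footage around unexplained
captures.

## Matching and verification logic

Video events are matched to head acceleration events by greedy
nearest-in-time one-to-one pairing within a configurable tolerance
(default ±2 s; the real synchronization uses a world clock stamped at video
start, so residual offsets are small). Labels follow the study's
verification logic: a matched, clearly-coded direct head impact is a TP
(verified head impact); an unmatched direct head impact an FN; a contact
event without head impact is a TN unless it absorbed an HAE (then the HAE is
an FP); an HAE matching nothing is an FP; unclear events are held out of the
base table entirely. Scenario tables treat the unclear events wholesale: the
best case adds all of them to TP, the worst case to FP — reproducing the
published arithmetic exactly, even though only ~37% of unclear events had an
IMG capture; this mirrors the source analysis rather than re-deriving a
defensible intermediate.

## Statistics

Sensitivity is TP/(TP+FN), PPV is TP/(TP+FP); rates are reported per
athlete exposure at one decimal. Magnitude tables give per-stratum count,
median, IQR and a seeded percentile-bootstrap 95% CI of the median (2,000
resamples by default) — the published tables mix IQR and unspecified 95% CIs,
so both are emitted. Group contrasts use the two-sided Mann-Whitney
rank-sum test (exact for small untied samples, tie-corrected normal
approximation otherwise), normality checks the Shapiro-Wilk test, and
inter-rater agreement is raw percent agreement plus Cohen's kappa. No
multiple-testing correction is applied, matching the descriptive style of
the source analysis; treat the per-contrast p-values accordingly.

## What passing tests do and do not show

The generator emulates event *rates*, magnitude *laws*, sensor *rates and
noise*, and coding *imperfections*; it does not emulate biofidelic skull
dynamics, player-position-specific movement, soft-tissue or mandible
dynamics, chewing, or true broadband impact spectra. Recovery results
(sensitivity within binomial bounds of the configured truth; PLA recovered
within a few percent) therefore validate the *pipeline logic and its
statistics* — trigger/window arithmetic, filtering, the rigid-body inverse,
matching and the accuracy analysis — under controlled conditions. They do
not certify any physical device, and PRA recovery in particular carries a
known few-percent low bias because a haversine angular-velocity pulse
sampled at 800 Hz and linearly upsampled loses derivative amplitude.

## Problem sizes used by the test suite

The acceptance tests run 50 replicate seasons of 61 condensed exposures
(~2,000 contact events each) for the sensitivity-recovery experiment,
100,000 draws for sampler calibration, and constructed signals elsewhere;
the full suite completes in well under half an hour on one CPU. The
bootstrap in replicate-season reports is reduced to 25 resamples, which
affects only confidence intervals that those tests do not read.

## Known limitations

* The trigger-axis semantics of real devices ("absolute value across one of
  the accelerometer's three axes") are ambiguous; the pipeline triggers on
  the raw resampled left accelerometer, configurable per sensor.
* Angular acceleration differentiates the filtered, upsampled gyroscope
  stream; devices may use proprietary schemes.
* Sensor fusion is an unweighted mean; a least-squares rigid-body fit over
  all nine accelerometer channels would be the natural extension.
* The best-case/worst-case scenario arithmetic follows the published
  convention of moving *all* unclear events, not only those with captures.
* Handling-artifact and vocalization waveforms are stylized stand-ins; the
  published classifier that screens real captures is proprietary and out of
  scope, represented here by the 300 Hz low-pass screen.
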