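---
title: "Comparing accelerometer-based vGRF estimators: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing accelerometer-based vGRF estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vertical ground reaction force (vGRF) during running is the gold-standard
kinetic signal of gait analysis, but force plates are captive to the lab.
Many published methods estimate vGRF features from a single body-worn
accelerometer (shank, hip, or sacrum): the impact ("first") peak, the
loading rate to that peak, the active ("second") peak, the stance average,
and the full stance time series. accelGRF implements 27 such methods behind
one registry, the IMU processing chain they require, the force-plate
feature definitions they are scored against, and the linked-replicates
agreement statistics used to compare them. Because raw gait datasets of
this kind are typically access-restricted, the package ships a synthetic
running-gait generator so that every stage is testable end to end without
any download; real data enter as delimited per-stance time-series tables
with a participant metadata table (the fixture schema written by
`write_dataset_csv()`).

## The agreement model

Each trial is measured by every method and by the force plate, so
per-trial variation is shared across methods ("linked replicates"). For a
response $y_{mpt}$ (method $m$, participant $p$, trial $t$; either the
measurement or the error against the gold standard):

$$y_{mpt} = a_m + b_p + C_{mp} + D_{pt} + \varepsilon_{mpt},$$

with fixed method intercepts $a_m$, random participant effects $b_p$, a
method-by-participant interaction $C_{mp} \sim N(0, \tau_m^2)$, shared
participant-by-trial effects $D_{pt}$, and method-specific residuals
$\varepsilon_{mpt} \sim N(0, \sigma_m^2)$. From the fitted components:

- repeatability coefficient $\mathrm{RC}_m = 2.83\,\sigma_m$ (the
  difference of two replicates has SD $\sigma\sqrt2$; $2.83 =
  \mathrm{round}(2\sqrt2, 2)$);
- limits of agreement $\mathrm{LOA}_m = 1.96\sqrt{\tau_0^2 + \tau_m^2 +
  \sigma_0^2 + \sigma_m^2}$, where $\tau_0, \sigma_0$ are the gold
  standard's own components.

`fit_linked_replicates()` fits this by REML (nlme: a `pdBlocked`
participant-level structure of a shared intercept, a `pdDiag` per-method
interaction, and a `pdIdent` trial effect, with `varIdent` residual
strata). Two formulations are supported and `formulation = "measurement"`
is the default: reference (force-plate) rows enter as their own method so
$\tau_0, \sigma_0$ are estimated; `"error"` models errors directly with
the reference components pinned at zero. Methods without internal
variation (e.g. the reference entered as per-trial time-series RMSE,
identically zero) are pinned at zero rather than estimated, and a model
with a single estimable method drops the trial term, which is then
confounded with the residual.

Two numerical choices matter in practice. First, the response is always
standardized internally (components are rescaled on the way out), which
makes the fit exactly scale-equivariant and keeps the optimizer
(`nlminb`, falling back to `optim`) on a well-conditioned surface.
Second, `agreement_by_method()` fits each method *paired with the
reference* instead of one joint model across dozens of methods: the LOA
formula only ever combines one method's components with the reference's,
pairwise fits are the standard Bland-Altman practice against a gold
standard, and a 26-method joint fit (26 interaction variances plus 26
residual strata) is numerically fragile for no inferential gain. The
joint fit remains available through the `methods` argument.

One-sample t-tests per method and feature are corrected with the
Benjamini-Hochberg step-up rule across the whole family at $q = 0.05$
(the procedure is not named in the source literature beyond "FDR"; BH is
the field default). Tests are trial-level by default. Condition-effect
models add fixed effects of running speed (m/s), surface (0 = floor, 1 =
track), and foot strike angle (rad) to a per-method error model with a
random participant intercept; Wald p-values use the normal approximation,
which is adequate at the trial counts involved (hundreds of residual
degrees of freedom). These models are fitted per
method: condition effects are method properties, and per-method fits keep
each model small and interpretable.

## The gold-standard feature definitions

Stance is bounded by a 10 N threshold on the 50 Hz low-passed vertical
force (longest supra-threshold run; an input that never drops below the
threshold is treated as a full-window stance so trimmed fixtures still
work). The impact peak is localized on a high-frequency (HiF)
reconstruction: Fourier components below 10 Hz are zeroed (hard mask on
the unpadded stance transform, so bin spacing is 1/stance-duration) and
the earliest local maximum of the HiF signal after 5% of stance marks the
first-peak time; the magnitude is read off the original force. A local
maximum must be strictly greater than its neighbouring distinct values; a
plateau is represented by its first sample.

One detail is easy to get wrong: even an impact-free stance leaks a few
percent of its amplitude into the $\ge 10$ Hz bins, because the windowed
half-sine is a rectified sine whose endpoint kinks carry harmonics
$\propto 1/(4k^2-1)$. An unthresholded "earliest HiF maximum" would
therefore *always* report a first peak, and forefoot stances would never
be labelled impact-free. `hif_first_peak()` consequently requires a
qualifying peak to reach `min_rel_amplitude` (default 5%) of the peak
force; genuine impact transients sit well above this, leakage ripple and
filtered noise well below. Setting it to 0 restores the unthresholded
detector.

The loading rate is the secant slope over 20-80% of the onset-to-first-
peak interval (linear interpolation at the fractional sample times); the
second peak is the largest local maximum after the first-peak time
(global maximum when no first peak exists); the average is the arithmetic
mean over stance.

## The IMU chain

Processing follows the conventional offline order: affine calibration;
quiet-period detection (angular velocity below 0.5 rad/s and jerk below
0.01 m/s^3 for at least 100 ms); bias removal (gyroscope mean over the
quiet range; accelerometer magnitude deviation from 1 g removed along the
quiet gravity direction — a per-axis rule would need a known orientation,
which is what the quiet range is for); dual-range fusion replacing whole
frames whose primary accelerometer exceeds 15.5 g with the wide-range
secondary channel (whole frames, so no frame mixes calibrations); a
zero-phase 4th-order 50 Hz Butterworth filter; Madgwick orientation
estimation with gravity removal; and coordinate transforms.

Numerical notes:

- *Zero-phase filtering.* Offline biomechanics uses forward-backward
  filtering to preserve peak timing. `signal::filtfilt` applies no edge
  padding, so `lowpass_filter()` odd-reflection-pads (at least 100
  samples) to absorb the zero-initial-condition start-up transient; DC
  signals then pass through unchanged to ~1e-9.
- *Jerk.* The jerk threshold is applied to the raw derivative of the
  acceleration magnitude. Smoothing the magnitude first is available
  (`smooth_cutoff`), but a zero-phase smoother leaks motion energy
  backwards into adjacent quiet samples and shrinks detected quiet
  ranges, so it is off by default. The 0.01 m/s^3 default is only
  satisfiable on genuinely still data; the generator's quiet-standing
  prefix is ideal (noiseless) for exactly this reason, and real
  recordings may need a larger threshold.
- *Madgwick filter.* Gain $\beta = 0.1$ by default, initialization from
  quiet-standing gravity with zero yaw, implemented in a +y-up world
  frame to match the package's coordinate convention (sensor +x
  anteroposterior, +y longitudinal, +z right). $\beta = 0$ integrates
  the gyroscope only, which is exact for noiseless rotation-free data and
  is what the end-to-end machine-precision oracle uses. Zero-norm
  accelerometer frames skip the gradient correction.
- *Segment coordinate system (SCS).* The mediolateral axis is the first
  principal axis of angular velocity during running (an error with a
  variance-ratio diagnostic when the PCA is isotropic); the longitudinal
  axis is quiet-standing gravity orthogonalized against it. The sign of
  the mediolateral axis is chosen so the mean anteroposterior
  acceleration during running is positive along +x (forward), with ties
  broken toward the raw sensor axes. The SCS is a sensor-to-segment
  rotation and is applied to the *sensor-frame* gravity-free
  acceleration (rotating the inertial-frame vector instead would mix
  frames). The tilt-corrected system (TCCS) keeps the inertial vertical
  and aligns +x with the horizontal projection of progression.

## The estimator families

The 27 methods fall into four families. DIRECT methods multiply
acceleration by mass ($F = m\,g_0\,(a_y + 1)$ for the vertical selector;
for resultant selectors gravity is re-added on the vertical axis before
taking the magnitude, which reproduces the vertical force exactly on
pure-vertical motion) after a method-specific cutoff (5/10/30 Hz for the
Day variants, 10-25 Hz or raw for the Wundersitz variants). Regression
methods (Neugebauer, Charry, Kiernan, Higgins, Veras) fit OLS of a gold
feature on the peak of the selected signal (or the peak signal *rate* for
loading-rate methods), mass, and their interaction; the Higgins forms add
height and leg length; the Neugebauer form fits the log target and
back-transforms. The exact functional forms of the source publications
are method-level defaults visible in each spec's `designs` field and are
overridable, since this package's contribution is the comparison harness,
not a transcription of thirteen papers. The Kim family projects the
body-weight-normalized force series (resampled to L = 100 points) on K =
10 sine basis functions $\sin(k\pi\tau)$ and regresses each coefficient
on signal features (peak/mean acceleration and contact time, or the
displacement excursion from double integration with per-stance linear
velocity detrending); aliased feature columns drop out with zero weights.
The Pogson family is a small fully connected network (two tanh layers of
32 units, full-batch Adam, fixed epoch budget, seeded and deterministic)
from the three resampled stance channels plus mass and contact time to
the L-point series in body weights; the "xynorm" variant scales the
resampled x and y channels to unit peak absolute value per stance.
Estimated series are produced on the normalized grid and resampled to the
stance's true duration (taken from the stance window, never from the
force) before features are derived from them with the gold-standard
operations.

Trainable methods are always fitted inside `loo_estimate_all()`: for each
participant, models train on all other participants' stances and predict
the held-out participant's, so no estimate ever touches its own
participant's data (fold membership is recorded and asserted). Training
targets are the gold-standard features.

A caveat on the DIRECT cutoffs: the intuition "a more restrictive cutoff
never increases the peak" is not a theorem for stance-windowed signals. A
5 Hz 4th-order filter's settling time is comparable to a 0.3 s stance,
and finite-window edge effects can overshoot a smooth active peak by a
few percent (we measure ~3% against the 10 Hz variant). The ordering
holds cleanly when the peak is impact-dominated, which is what the tests
assert.

## The synthetic generator

The generator's default design is a full overground running protocol: 74
participants, 2 surfaces, 3 self-selected speed classes, 2 sides, 5
stances per cell (4440 trials), 1000 Hz synchronized force and tri-axial
accelerometer/gyroscope signals at shank, hip, and sacrum, with
anthropometrics and foot strike angles per participant. Self-selected
speed classes have no canonical numeric values, so the class means are
generator choices: 2.7, 3.3, and 4.2 m/s (SD 0.25/0.30/0.45), typical of
recreational overground running. Contact time falls linearly with speed
(0.35 s at 2.5 m/s to 0.22 s at 5 m/s, floored at 0.15 s). Cohort
distributions (mass ~ N(66, 12) kg truncated above 40, height ~ N(1.70,
0.09) m, participant-mean foot strike angle ~ N(0.15, 0.12) rad) are
configuration defaults chosen to be physiologically plausible, not claims
about the original cohort.

The force model is a raised half-sine active component with amplitude
$m\,g_0\,(1.4 + 0.25\,v)$ body weights at speed $v$ (so the active peak
grows with speed), plus a gamma-shaped impact transient peaking at 13% of
stance with amplitude $m\,g_0 \cdot \max(0,\ 3.0\,(\theta - 0))$ body
weights at foot strike angle $\theta$ (so forefoot strikes, $\theta <
-0.03$ rad, carry no impact component and rear-foot strikes a prominent
one). Both components carry participant-level log-normal multipliers (SD
0.08). The surface multiplier defaults to 1 — no surface effect — consistent
with the common finding that level running surfaces rarely explain vGRF
estimation error; it is configurable for power studies. All latent features are
closed-form (the latent first peak applies the HiF rule to the noiseless
composite, since the raw composite's earliest local maximum sits ~20 ms
after the transient center and would not be comparable to the measured
definition).

COM placements obey Newton's second law by construction: with all noise
terms zero, $m\,g_0\,(a_y + 1)$ reproduces the force series exactly
during stance, which gives the test suite a machine-precision end-to-end
oracle through the entire chain (generation, quiet detection, bias
removal, fusion, degravitation with $\beta = 0$, SCS, windowing, direct
estimation). The shank adds a sharp impact spike (5-15 g, scaling with
the impact amplitude; the primary channel clips at its 16 g range) so
saturation fusion is exercised. Gyroscope signals are dominated by a
mediolateral oscillation during stance so SCS extraction is exercised.

What the generator does *not* emulate — and therefore what passing tests
do and do not show: soft-tissue wobble and its frequency content are
reduced to a fixed-frequency ripple plus white noise; the gyroscope
oscillation is not propagated into the accelerometer's gravity direction
(the segment does not really rotate), so Madgwick tracking errors are
milder than on real data; the quiet prefix is ideally still; and the
bias / RC / LOA magnitudes that these methods achieve on real runners are
*not* reproducible from synthetic data, because they are dominated by
real soft-tissue dynamics. Tests on this generator
validate the machinery — definitions, transforms, training isolation, and
the statistical estimators — not field performance.

## Problem sizes

The test suite and examples run desk-scale configurations chosen as the
package's own defaults for development: 2-5 participants with 1-2 stances
per cell for pipeline smoke tests, 200 random stances for the
detector-versus-oracle equivalence checks, 60 participants x 30 trials x
2 methods for variance-component recovery (averaged over 15 replicate
simulations, since a single draw of the interaction SD at these nuisance
levels carries 30-50% sampling noise), and 200 null datasets of 20
participants x 12 trials for the condition-model type-I calibration. The
full 74-participant design is generated for design-count checks only;
`generate_dataset()` at full scale produces ~4440 signal-bearing stances
and is intended for batch use.

## Known limitations

- The variance-components model assumes normal, homoscedastic effects
  within method; heavy-tailed derived features (loading rates from
  estimated series can be wild) strain it. Methods with fewer than three
  usable trials per feature are dropped from the fit with a warning.
- Wald p-values use the normal approximation; at very small cohort sizes
  a Satterthwaite-style correction would be more conservative.
- The HiF qualifying-peak floor (5% of peak force) is a detector design
  choice; analyses that require the literal unthresholded rule should set
  `min_rel_amplitude = 0`.
- No magnetometer fusion, no online operation, no treadmill/incline
  gaits, and no centre-of-pressure or shear-force processing.
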