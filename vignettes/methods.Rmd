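---
title: "Methods: kinematics, fusion metrics, and inference in seqreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, fusion metrics, and inference in seqreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind each stage of
the package, the assumptions they make, and the numerical and design
choices a user should know before trusting the outputs on their own data.

## Task geometry

The workspace is a central via target with four targets around it:
targets 1 and 4 at 10 cm on the y-axis, targets 2 and 3 at 5 cm with a
126° angle between them (both configurable). A trial traverses
via–1–via–3–via–2–via–4–via: 9 waypoints, 8 reaches, 7 via transitions.
The coordinate frame places the origin at the via with +y toward
target 1; all metrics in the package are invariant under rigid rotation
and translation (this is covered by tests), so the frame and the
orientation of targets 2/3 (`mirror`) are conventions, not assumptions.

## Velocity and segmentation

Speed is the magnitude of the planar first derivative of position,
computed by central finite differences (one-sided at the ends), then
smoothed with a Gaussian kernel of standard deviation **2 samples**
(`smoothing_sd_samples`, i.e. ~18 ms at the nominal 110 Hz), truncated
at 4σ with reflected boundaries. Expressing σ in samples follows the
common practice of motion-capture pipelines run at a fixed sampling
rate; at other rates the user should rescale σ if they want the same
temporal bandwidth.

Segmentation walks the reach sequence with a proximity rule: segment *k*
ends at the *first* sample strictly within **2 cm**
(`proximity_radius`) of the next expected waypoint; the transition
window is the maximal contiguous run of samples inside that 2-cm region
around the boundary. Two consequences matter:

* a waypoint never approached within 2 cm raises an incomplete-trial
  error naming the missing waypoint (such trials are excluded from batch
  analyses, mirroring the abort-and-repeat rule of the task);
* the minimum-velocity search window is the 2-cm proximity region, not
  the 1-cm-diameter target itself. The narrower reading would shrink the
  window and can only raise `v_min`; with the package's simulator the
  difference is negligible because the speed minimum sits at the
  waypoint passage itself.

Per-trial measures: `v_max` per segment (and its spatial location),
`v_min` per transition window, their means over the 8 segments and 7
transitions, movement time (first sample strictly >2 cm from the start
position, to the first proximity entry of the final waypoint — the same
2-cm threshold the reaction-time definition uses), and reaction time
(trial onset to that exit).

## Fusion index

Per transition, `FI = 1 − (m − v_min)/m` with `m` the mean of the two
adjacent peaks, i.e. `v_min/m`; a trial sums 7 transitions (maximum 7).
Noise can push `v_min` above `m`; raw values outside [0, 1] are clamped
with a warning rather than propagated, since values above 1 have no
kinematic interpretation. The index is scale-invariant, so it compares
across movement speeds.

## Spatial reorganization (radial distance)

For each sliding window of **10 trials** (stride 1) and each reach
except the first and last, the (x, y) locations of the per-segment speed
peak are pooled; a principal-axes ellipse is fitted (sample covariance,
principal components scaled by the χ²(2 df) 95% quantile, centroid =
sample mean, which is the intersection of the ellipse axes under this
construction); and the distance `d` from the centroid to the **central
via point** is converted to `RD% = 100·(1 − d/L)` with `L` the reach
length, clamped to [0, 100]. The via point is the anchor because every
included reach starts or ends there: discrete bell-shaped reaches put
the peak near the reach midpoint — `d ≈ L/2`, RD ≈ 50% (the tests check
the 45–55% band) — and fully fused passes put the peak near the via
passage, RD → 100%.

The RD–fusion relation is *curvilinear*, not linear: at low fusion the
peak stays near the reach midpoint even as the via dip fills in, and
only once transitions are substantially fused does the peak location
drift toward the via. The package's qualitative checks therefore test
the positive RD association over the upper half of the fusion range
(plus the endpoint ordering), and `piecewise_fit()` — a continuous
two-segment hinge fit with the interior knot found by a quantile grid
search refined with golden-section optimization — is provided to locate
the inflection in FI–RD scatters.

## Minimum-jerk model

The reference trajectory minimizes `½∫(|x⃛|²+|y⃛|²)dt` subject to
passing through the via points with zero velocity and acceleration at
the trial's start and end (participants begin and end stationary). For
*fixed* passage times the optimum is solved exactly: the Euler–Lagrange
equations make each axis a piecewise quintic that is C⁴ across interior
via points, so the coefficients come from one linear system per axis
(the test suite verifies optimality against perturbations inside the
C²-feasible set, the closed-form point-to-point profile
`v_peak = 1.875·L/T`, and the jerk cost `360·L²/T⁵`). Passage times are
then optimized by Nelder–Mead over a softmax parameterization of
segment durations (positive, summing to the movement time), initialized
proportional to the straight-line distances; only the total movement
time is taken from the data, passage times are never copied from the
observed trial. Since uniform time rescaling leaves the optimal path
unchanged, the normalized model profile is computed once per geometry
and reused for all trials, and the jerk cost is rescaled as `T⁻⁵`.

Model fit is the MSE between the observed and predicted speed profiles
after (1) trimming both to their moving span (first to last crossing of
5% of the profile peak — symmetric trimming matters, otherwise the
stationary lead-in of recorded data biases the comparison), (2) mapping
time to [0, 1], (3) normalizing amplitude to unit peak (unit mean is
available via `amplitude = "integral"`), and (4) linear interpolation to
**N = 500** points. Scalar speed is compared rather than per-axis
velocity so the score does not double-count path differences already
visible in the speed profile.

## Spectral arc length

SPARC is the negative arc length of the zero-padded
(`2^(nextpow2 + 4)`) magnitude spectrum of the speed profile, DC-
normalized, restricted to ≤ **20 Hz** with an adaptive cutoff at the
last frequency whose normalized magnitude exceeds **0.05**, over a
normalized frequency axis. These are the established defaults of the
published measure; the tests verify its sampling-rate invariance and
that added band power strictly lengthens the spectral arc. Corrected
trials — those containing a corrective submovement to re-acquire a
missed target — are excluded from MSE and SPARC analyses
(`exclude_corrected()` reports the count and percentage), because extra
velocity peaks inflate both measures for reasons unrelated to the
quality of the intended movement.

## Reward schedule

`closed_loop_feedback()` ranks the current movement time against the
**20** preceding trials: the percentile is the fraction of reference
times *strictly slower*, mapped through ≥90% → 5p, [80, 90) → 4p,
[60, 80) → 3p, [40, 60) → 2p, [20, 40) → 1p, <20% → 0p. The current
trial is ranked *against* the window, not inserted into it; with 20
references both readings reproduce the printed cut points, and strict
inequality resolves ties conservatively (a tie earns nothing — ties are
measure-zero for continuous movement times anyway). Random feedback
draws uniformly from a pool of previously awarded payouts, preserving
the marginal reward distribution while decoupling it from performance.

## Bootstrap learning-curve inference

`bootstrap_fit()` resamples *participants* with replacement to the
original group size (1,000 draws by default), averages the resampled
participants trial-wise, and refits the curve family each draw: `poly1`
(`p1`·trial + `p2`), `exp1` (`a·exp(b·x)`), `power1` (`a·x^b`).
Intervals are percentile-based (2.5/97.5%). Nonlinear families are fit
by Levenberg–Marquardt with log-space initialization; a failed draw is
retried from jittered starts and more than 5% failures is an error
rather than a silent bias. Group differences use the per-draw paired
difference CI as the primary criterion (per-group CIs are also reported
for the more conservative non-overlap reading). Trial-wise means use
whichever participants have data on that trial. `baseline_correct()`
and `early_training_mean()` support the invigoration-vs-learning
decomposition: intercept-like rapid effects show in the first-trials
mean, learning in the slope.

## The synthetic generator

The generator exists so that every stage is testable against known
ground truth. One trial is built from a "knot plan": the fully fused
C⁴ via-point pass is solved once (distance-proportional passage times;
the outer optimization is reserved for the analysis model), and each
interior waypoint receives boundary velocity and acceleration equal to
`fusion_level` times the fused values, plus a dwell of
`(1 − fusion_level)·dwell_s` realized as a linear coast through the
waypoint at the boundary velocity (a true stop at fusion 0). This makes
the construction continuous in the fusion level with exact endpoints:
fusion 0 is discrete point-to-point minimum-jerk reaches with full
stops, fusion 1 is exactly the fused pass, and the per-trial fusion
index is monotone in the dial. The trajectory is then globally
time-rescaled so the *measured* movement time (2-cm exit to final 2-cm
entry) equals the configured `movement_time_s`, sampled at **110 Hz**,
and optionally degraded with isotropic Gaussian position noise.
Corrective submovements are injected by routing one reach past its
target (a flyby at a guaranteed clearance above the 2-cm proximity
radius, a stop beyond it, then a corrective re-acquisition), which is
what the corrected-trial detector looks for: a local minimum of the
distance-to-waypoint above the proximity radius followed by a rebound
of at least 0.5 cm and a later re-entry.

Dataset-level defaults model a learning experiment: movement time
`intercept + slope·trial + participant offset + trial noise` truncated
below at a floor (defaults: 5 s intercept, −0.002 s/trial, 0.3 s
participant SD, 0.2 s trial SD), and a per-trial true fusion level
following a linear trend clamped to [0, 1]. The defaults put simulated
behaviour in the range of slow multi-target sequences (4–6 s trials,
peak speeds of tens of cm/s) rather than rapid single reaches.

What the generator does **not** emulate: biomechanics (no arm model,
stiffness, or signal-dependent noise), reaction-time cognition (the
lead-in is a constant), error trials other than the scripted corrective
submovement, and trial-to-trial spatial variability of the *path* (noise
is white position noise, so windowed peak-location scatters are tighter
than real data). Passing the package's tests therefore demonstrates the
correctness of the measurement and inference code, not that real
participants behave like the generator.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with typed conditions
(`seqreach_parameter_error`, `seqreach_data_error`,
`seqreach_incomplete_trial_error`, `seqreach_fit_error`); degenerate
peak-location scatters yield a zero-axis ellipse with a valid centroid;
all stochastic functions accept a seed and leave the caller's RNG state
untouched. Proximity predicates use strict inequalities and
first-sample-wins tie-breaks. The test suite runs its heavier checks at
deliberately modest sizes chosen to exercise the statistics without
waste: bootstrap coverage uses 200 replicate groups of 15 participants ×
200 trials at 200 bootstrap draws; the radial-distance calibration uses
30–50 noiseless trials; the qualitative fusion sweep uses an 11-point
fusion grid. The defaults users see (`n_boot = 1000`, 10-trial windows,
20-trial reward windows, N = 500 interpolation) are the standard
analysis values.

## Known limitations

* The corrected-trial detector is tuned to corrective reversals of at
  least ~0.5 cm rebound; subtle online corrections that never leave the
  proximity region are not flagged.
* The piecewise (hinge) fit assumes exactly one interior knot, as in
  the FI–RD analysis it serves; it is not a general spline fitter.
* The minimum-jerk outer optimization is a local search from
  distance-proportional times; for the reaching geometries it serves it
  converges robustly, but pathological via layouts may need a supplied
  `passage_times` start.
* SPARC values depend on the windowing of the speed profile; compare
  values only across profiles trimmed the same way (`moving_window()`).
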