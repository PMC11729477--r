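---
title: "Comparing lumbar-IMU and camera-derived CoM accelerations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lumbar-IMU and camera-derived CoM accelerations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcom)
```

## The measurement problem

A single accelerometer at the fifth lumbar vertebra (L5) is a popular,
inexpensive proxy for whole-body center-of-mass (CoM) motion during
walking. But the CoM of a multi-segment body is an equilibrium point that
migrates with posture, while the sensor is bolted to one landmark on the
pelvis. `gaitcom` implements the complete chain needed to quantify how
much the two disagree: a segmental CoM model on the camera side, signal
conditioning and gait-event detection on both sides, gait-cycle
normalization, and two complementary statistical comparisons — pooled
agreement statistics (Pearson, Bland–Altman) on accelerations in physical
units, and one-dimensional statistical parametric mapping (SPM) on
amplitude-normalized waveforms.

Three measurement conditions are compared throughout: **IMU** (the sensor's
tri-axial acceleration), **ML5** (a motion-capture marker placed on the
sensor, twice differentiated — isolating differences that come from the
numerical differentiation of position data rather than from the CoM model),
and **CoM** (the 13-segment weighted-sum model, twice differentiated).
Axes are fixed as X = anteroposterior (AP, the walkway axis),
Y = mediolateral (ML), Z = vertical / superior–inferior (SI).

## The segmental CoM model

Whole-body CoM position per axis is the weighted sum
$x_0 = \sum_i (m_i/M)\,x_i$ over 13 segments: head+neck, trunk, pelvis, and
left/right upper arms, forearms+hands, thighs, shanks and feet. Mass
fractions $m_i/M$ and segment-CoM position ratios come from the classical
Dempster cadaver tables as tabulated in Winter's textbook (head+neck 0.081,
upper arm 0.028, forearm+hand 0.022, thigh 0.100, shank 0.0465, foot
0.0145). The combined trunk+pelvis fraction of 0.497 is split 0.355/0.142
between a thorax-dominated trunk segment and the pelvis, in line with
common multi-segment conventions. Segment endpoints are centroids of named
markers — e.g. the trunk runs from the mid-shoulder point to the mid-ASIS
point — rather than regression-based joint centres; this keeps the model a
pure function of the marker set and is the main simplification relative to
full laboratory practice. The whole table ships as an editable object
(`default_body_model()`, YAML round trip via `write_body_model()`), and the
tests pin the shipped values: fractions must sum to 1 within $10^{-6}$ and
paired segments must be symmetric.

## Signal conditioning

* **Filtering.** "Fourth-order zero-lag Butterworth" is read the
  conventional way for gait analysis: a 2nd-order digital design applied
  forward and backward, doubling the effective order and cancelling phase.
  `filter_spec(order, cutoff, rate, convention = "halved")` makes that
  doubling explicit and the alternative (`"direct"`) available. Defaults:
  markers 4th order / 12 Hz at 240 Hz; IMU 2nd order / 12 Hz at 128 Hz.
  Endpoint transients are suppressed by odd (mirror) reflection padding of
  three characteristic lengths (`3 * rate / cutoff` samples); the first and
  last gait cycles are additionally discarded downstream, so residual edge
  effects never reach the statistics.
* **Differentiation.** Accelerations come from position by the
  finite-difference scheme: central second differences in the interior,
  second-order one-sided stencils at the ends (exact on quadratics,
  truncation $O(\Delta t^2)$). Filtering is applied to marker positions
  *before* CoM summation and differentiation; since both the filter and
  the weighted sum are linear this ordering is a convention, fixed here so
  every position stream is conditioned identically.
* **Gravity.** The vertical IMU channel is corrected by subtracting
  exactly 9.81 m/s²; no latitude correction.

## Gait events

Camera-side heel strikes use a 20 N vertical-force rising threshold when
force data exist, otherwise local minima of the heel-marker height with a
refractory period of half the dominant stride period (estimated from the
autocorrelation peak in the physiological 0.5–2 s stride band, requiring a
peak correlation above 0.2 so aperiodic input fails loudly). IMU-side
initial contacts follow the Gaussian continuous-wavelet method for trunk
accelerations: detrend the vertical channel, integrate, then differentiate
by convolution with a Gaussian-derivative kernel at scale one tenth of the
stride period; minima of the transform are contacts. The transform yields
one minimum per *step* (both feet); because a cycle is defined same-foot
heel-strike to heel-strike, the detector splits the alternating step
stream into its two parities and keeps the deeper one, returning one event
per stride (`per = "step"` exposes the raw stream). A 30% refractory at
the step level — rather than 50% of the stride — avoids a tie at exactly
half a stride between opposite feet. All extrema are refined to sub-sample
precision by parabolic interpolation, which matters for cross-rate
comparisons (128 Hz sampling alone would quantize events to ±3.9 ms).
Cross-system pairing removes the median clock offset and reports, never
drops, unpaired events.

## Cycle normalization

Cycles run heel-strike to same-foot heel-strike (right foot by default).
The first and last cycles of each trial are trimmed whenever at least one
cycle remains (filter-edge and detection-boundary hygiene); with only two
events the single cycle is kept with a warning. Each cycle is resampled by
cubic splines onto 101 nodes (0%…100%) — interpolation only, the cycle
carries guard samples so boundary nodes are never extrapolated. Per
subject and condition, the statistical substrate is one 101-node, 3-direction
curve: the ensemble average over that subject's interior cycles. Amplitude
normalization (divide by the largest absolute extreme, mapping the curve
into $[-1, 1]$) is applied per subject, condition and direction on that
ensemble-average curve — matching the per-subject curves that enter the
group-level SPM — and only for the SPM magnitude comparison. Agreement
statistics pool the *physical-unit* curves: reported biases are in m/s²,
which amplitude-normalized data could not produce. With a complete cohort
the pooled count is n_subjects × 101 nodes × 3 directions (4848 for 16
subjects), which implies one curve per subject and condition; per-trial
pooling would multiply that count and is intentionally not the default.

## Agreement statistics

Pearson's r (with the two-sided t-transform p-value) and Bland–Altman
analysis are computed on the pooled pairs, all three directions together;
per-direction labels are retained for plotting. Differences are `a - b`,
the bias is their mean, and the limits of agreement are bias ± 1.96 × SD
(sample SD). No outlier removal is performed. Points within a subject are
not independent, so the simple pooled limits are descriptive rather than
strictly inferential; a repeated-measures correction is deliberately out
of scope to keep the analysis aligned with standard practice for this
comparison.

## 1D SPM: fields, smoothness, thresholds

At each node, a one-way repeated-measures ANOVA partitions variance into
condition, subject and residual (subject × condition) components;
$F = MS_{cond}/MS_{resid}$ with $(k-1, (k-1)(n-1))$ degrees of freedom —
(2, 30) for 3 conditions and 16 subjects. Sphericity is assumed (no
Greenhouse–Geisser correction), the usual default for one-way
repeated-measures SPM. Post-hoc comparisons are paired-t fields at
Bonferroni-corrected α = 0.05/3 ≈ 0.017, two-tailed (the threshold is
solved at α/2 and applied to |t|).

Residual smoothness is estimated as the field FWHM: residual curves are
normalized pointwise by their root sum of squares, and the mean root
squared forward difference between adjacent nodes gives resels per node;
$FWHM = \sqrt{4\ln 2 / \langle g^2\rangle}$ in the standard 1D
random-field form. Forward differences are essential: on white noise this
estimator has median FWHM ≈ 1.2 nodes (the tests pin the [0.8, 1.5]
band), while central differences would see an artificially smooth field.
Resels are (number of nodes − 1)/FWHM.

The critical threshold solves
$\;P_{tail}(u) + \text{resels}\cdot\rho_1(u) = \alpha\;$
to $10^{-8}$, where $\rho_1$ is the 1D Euler-characteristic density and
the point tail probability is the boundary term; at zero resels this is
the ordinary single-comparison quantile. For the F field the density
coefficient is $\sqrt{4\ln 2/(2\pi)}$ — a factor $\sqrt{2\pi}$ larger
than the Gaussian/t coefficient $\sqrt{4\ln 2}/(2\pi)$ — which the
package verifies two independent ways: analytically, a $k=1$ F field must
equal twice the one-tailed t density because $F = t^2$; and empirically,
the family-wise type-I error over 1000 smooth-null simulations must land
in [0.03, 0.07] at α = 0.05 and the threshold must agree with a
1000-permutation (within-subject label shuffling) oracle within 10%. Both
checks run in the test suite and the acceptance script. Suprathreshold
clusters are maximal runs of nodes above the threshold, reported in % of
the gait cycle with RFT expected-cluster p-values; the headline inference
is threshold exceedance, and each direction is analyzed as its own 1D
field.

Degenerate designs are flagged rather than forced: if the residual mean
square vanishes (numerically identical subjects) the F field is reported
as 0/∞ per node with inference suppressed, and paired-t RFT inference
requires at least 3 subjects because with one denominator degree of
freedom the t-field EC density does not decay, so no finite threshold
exists.

## The synthetic cohort: what it emulates, and what it does not

The generator (`gait_sim_config()`, `generate_cohort()`) builds a 13-link
walker whose ~21 markers sit exactly at the model's segment endpoints and
follow closed-form harmonic trajectories: all markers share a common
translation (vertical and AP fluctuation at twice the stride frequency —
one bounce per step — about 2 cm and 1 cm peak-to-peak respectively, a
1.2 cm stride-frequency vertical component expressing left/right step
asymmetry, and 4 cm peak-to-peak ML sway at stride frequency); limb
markers add AP swing at stride frequency in left/right antiphase (up to
~36 cm peak-to-peak at the feet), so paired-limb motion cancels exactly in
the weighted CoM; and heel/toe/ankle markers lift once per stride with the
right-heel height minimum defining the heel-strike ground truth
analytically. The pelvis markers carry additional *local* motion
(ML ~1 cm at stride frequency, small AP/vertical components) that the
rest of the body does not share: this is the controlled ground-truth
discrepancy between the L5 sensor and the whole-body CoM, since the
sensor inherits it fully while the CoM inherits only the pelvis-adjacent
mass fraction (~0.43 through the pelvis, trunk-distal and thigh-proximal
endpoints). Defaults — 16 subjects, 12 strides per trial, stride
1.1 ± 0.05 s between subjects, 1.3 m/s progression, 240/128 Hz, 0.5 mm
marker noise, 0.03 m/s² sensor noise — are textbook-plausible values for
healthy adult self-selected walking; every amplitude is overridable via
`default_oscillations()`.

Because marker trajectories are harmonic sums, the exact CoM and its
derivatives are available in closed form (`analytic_com()`), the virtual
IMU is the exact second derivative of the pelvis-segment CoM (displaced
by the sensor offset, optionally rotated about the walking axis, gravity
added), and heel-strike times are exact. That buys strong oracles: the
pipeline must reproduce `truth_com` to $10^{-9}$ m, detect noise-free
events to sub-millisecond accuracy, and close the loop (r > 0.999,
|bias| < $10^{-6}$ m/s², no SPM clusters) when the pelvis-local motion is
switched off so IMU ≡ CoM by construction.

The generator deliberately omits much of real gait: no soft-tissue
artefact or marker dropout, no ground-reaction forces beyond an optional
synthetic square wave, no double-support asymmetries beyond the injected
harmonics, no within-trial stride-time variability, and smooth harmonic
(not impact-like) accelerations. Passing tests therefore demonstrate that
the *computational chain* is correct and calibrated — not that a real L5
sensor agrees with a real CoM to any particular degree; on laboratory
data the heel-strike transients and soft-tissue noise will widen all
agreement intervals.

## Numerical choices and problem sizes

Closure runs use stride SD = 0 (numerically identical subjects — the
degenerate-variance guard then suppresses SPM inference, which is exactly
the desired "no clusters" outcome for identical conditions), marker/IMU
rates of 960/256 Hz and order-4 filters for both streams, so that
discretization — finite-difference attenuation
$\sim(\omega\Delta t)^2/12$ and per-rate digital filter gain differences —
stays well below the $10^{-6}$ m/s² bias bound being verified. The test
suite and acceptance script size their simulations to run in about a
minute each on one CPU: 1000 smooth-null replicates for the type-I
calibration, 1000 permutations for the oracle comparison, 500 replicates
for Pearson calibration at ρ = 0.58 and n = 4848, 200 replicates for
post-hoc power, 100 noisy trials for event-detection robustness. Seeds
propagate deterministically (config seed → per-subject seeds), and
identical config + seed reproduces every output bit for bit.

## Known limitations

* The marker→segment endpoint mapping is a declared convention, not a
  reconstruction of any particular laboratory marker protocol.
* C3D input is not supported; the readers speak the tidy CSV dialects
  documented in `read_markers()` / `read_imu()`.
* Bland–Altman limits are computed under simple pooling (within-subject
  correlation ignored), matching common practice for this design.
* RFT assumes a stationary smooth Gaussian residual field; heavy
  non-stationarity in real residuals would call for the permutation
  threshold (provided) instead.
* The IMU parity selection assumes a consistent left/right asymmetry in
  vertical acceleration; perfectly symmetric gait makes the same-foot
  choice arbitrary (events would still be stride-spaced, but the foot
  label could flip between trials).
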