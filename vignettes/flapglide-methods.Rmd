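---
title: "Classifying at-sea behaviour, dives and foraging niche from seabird biologgers"
author: "flapglide authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying at-sea behaviour, dives and foraging niche from seabird biologgers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapglide)
```

## The problem

Chick-rearing petrels and other Procellariiformes are central-place
foragers: they commute from the nesting colony to marine feeding areas and
back, and the ecological questions — where do they feed, how hard do they
work, do the sexes differ — hinge on resolving behaviour at the scale of a
single second from animal-borne sensors. `flapglide` implements the full
analysis chain for deployments combining a GPS logger (fixes every 3–5
min), a 25 Hz tri-axial accelerometer, and optionally a 1 Hz pressure
sensor, as used on Westland petrels off New Zealand's South Island.

This vignette documents the models and procedures, the tunable parameters
and their defaults, the numerical choices, what the synthetic biologger
does and does not emulate, and the limitations a user should know about.

## Ethogram classification

**Static/dynamic decomposition.** Gravity changes slowly relative to body
movement, so a centered running mean over 1 s (25 samples at the default
rate; `decomposeWindowS`) estimates the static (postural) component on each
axis; the residual is the dynamic component. The window shrinks at the
record edges rather than padding, so static + dynamic reconstructs the raw
signal exactly everywhere. A 1 s window is the shortest that averages away
whole wingbeat cycles (~0.3 s) while following posture changes during
1–3 s prey strikes.

**Spectral features.** Flapping dominates heave-axis variance. For each 1 s
window we take the discrete Fourier magnitude spectrum of the raw heave,
exclude DC, and record the dominant cycle (inverse of the argmax frequency,
resolution 1 Hz) and its amplitude (2|X_k|/N). A windowed Fourier spectrum
gives the same dominant-cycle/amplitude features as continuous-wavelet
ethogram tools at 25 Hz while being simpler and exactly testable; the cost
is 1 Hz frequency resolution and spectral leakage for off-bin wingbeat
frequencies, neither of which matters for a two-cluster separation where
flapping amplitudes exceed the noise floor several-fold.

**Flap separation.** k-means with k = 2 (k-means++-style restarts via
`stats::kmeans(nstart = 10)`, fixed seed, so results are deterministic) on
the standardized feature pairs; the cluster with the higher mean amplitude
is flapping. A degenerate input (all features identical) flags nothing and
warns.

**On-water vs soaring.** Non-flapping seconds are rafting when the raw
per-second heave s.d. is at most `tauWaterG` (default 0.25 g) *and* the
static heave lies in the on-water band `waterBandG` (default
[0.45, 0.93] g); otherwise soaring. The physical picture: a logger on a
bird sitting on water shows a static heave offset from the airborne 1 g
baseline (mounting posture changes) plus slow wave modulation, while
dynamic variance stays low in both states. The band's upper edge sits
between the water (≈0.85 g) and air (1 g) baselines; its generous lower
edge keeps pitched-down (head under water) foraging postures classified as
on-water. These two constants are this package's own calibration on the
synthetic biologger; with real loggers they should be re-calibrated per
attachment, e.g. from the bimodal histogram of static heave. A 3 s
majority vote then removes single-second flicker, which per-second
windowing inevitably produces at bout transitions.

**Foraging.** A non-flying second whose *minimum* within-second pitch drops
below `pitchThresholdDeg` (−25°) is foraging; the minimum rather than the
mean is used so that strikes lasting 1–2 samples are not averaged away
(surface foraging events average ~1.2 s). Dive seconds from the pressure
channel are added to the foraging mask. Foraging seconds separated by at
most `eventGapS` (5 s) merge into one foraging event — the boundary is
inclusive, a 5 s gap merges and a 6 s gap splits — because the observed
distribution of inter-foraging intervals drops sharply beyond 5 s.

**VeDBA.** The Euclidean norm of the three dynamic axes, averaged per
second and per trip, proxies whole-body movement cost and should rank
foraging > flapping > soaring ≈ rafting.

## Dive analysis

Pressure converts to depth by `D = 0.01 (Pm − Pa)` (mBar to m of water).
Zero-offset correction subtracts a rolling lower-quantile baseline
(`driftQuantile` = 2% over `driftWindowS` = 10 min; a window longer than
the record degrades to a global baseline). The 2% quantile tracks the
surface rather than dive apexes because dives are rare and brief; with
sensor readings quantized at 5 mBar the quantile's downward bias is
≤0.025 m, negligible against the dive threshold.

A dive is a maximal submerged excursion whose depth strictly exceeds
`diveThresholdM` = 0.55 m — one body length, the smallest submergence
distinguishable from sensor noise at 5 mBar resolution. Excursion
boundaries use a wet threshold of 0.1 m (`surfaceEpsM`) so residual
±0.05 m surface noise neither bridges consecutive dives nor extends a
dive's start. Descent duration runs from the last surface sample to the
deepest sample; the fleet descent rate is the zero-intercept least-squares
slope of maximum depth on descent duration across dives (per-dive rates
are also reported).

For loggers without pressure, depth is estimated from dive duration as
`rate × duration / 2`: with V-shaped dives (linear descent and ascent at
equal rates) the descent occupies half the dive. The halving is an
inference — duration-based estimators are sometimes written with the full
duration — but it is the only reading consistent with the study system's
printed mean duration/depth pair (3.1 s, 1.3 m) at the 0.84 m s⁻¹ rate,
and it is exactly recoverable on the synthetic data.

Cross-sensor validation counts a pressure dive as detected when any
acceleration-derived foraging event overlaps it within ±`matchWindowS`
(2 s), reported as a percentage of pressure dives.

## Trip geometry

All geometry is geodesic on a sphere of radius 6371 km (haversine
distances, spherical polygon areas via `geosphere`); at foraging-trip
scales the spherical error is below 0.5%, in line with movement-ecology
practice. The 25 m s⁻¹ forward speed filter drops any fix implying an
implausible speed from the last retained fix (the first fix is always
kept); the pass is idempotent. Trips are maximal runs of fixes outside
`colonyRadiusKm` (default 1 km) of the colony, bracketed by the nearest
inside fixes; the radius rule stands in for a coastline landmask, which the
package does not ship — with a colony on a forested coastal range, a 1 km
radius removes colony-attendance fixes equally well. Runs of fewer than
three at-sea fixes are discarded as recording glitches. Tracks are
linearly interpolated at 1 s in latitude and longitude; home range is the
area of the convex hull of trip locations (duplicates dropped first;
collinear inputs are an error, not a zero).

Trip-duration modality uses the bimodality coefficient
`BC = (g² + 1) / (k + 3(n−1)²/((n−2)(n−3)))` with SAS-style (type 2)
small-sample skewness and kurtosis — a uniform distribution sits at the
5/9 benchmark, a normal at 1/3, and values above 5/9 suggest more than one
mode — together with 1- vs 2-component normal mixtures fitted by EM on
untransformed hours and selected by BIC (via `mclust`); component means are
reported as modes, and a degenerate two-component fit (near-zero variance
or weight) falls back to one component with a message.

## Habitat grid

Foraging seconds localized on the interpolated track are summed in square
cells of `gridCellDeg` = 0.04° (about 4 km² at these latitudes) and
standardized to percentages of the trip's foraging time, so they sum to
100 per trip. Cells are half-open, `[k·0.04, (k+1)·0.04)`, anchored at 0°:
an edge point belongs to the floor cell, and shifting all points by one
cell width shifts all indices by one. Environmental matching picks the
nearest raster cell of the temporally nearest covariate slice at the trip
mid-time; cells outside a layer's extent yield missing values, never
silent zeros. A Spearman rank-correlation matrix of matched covariates is
attached for collinearity screening, but no variable is dropped
automatically.

## Dimorphism and isotopic niche

Storer's index, `100 (m♂ − m♀) / (0.5 (m♂ + m♀))`, expresses dimorphism as
a percentage of the midpoint mean, avoiding a size effect; rounding to one
decimal happens only at reporting. The standard ellipse of a (δ¹³C, δ¹⁵N)
cloud has semi-axes √λ₁, √λ₂ from the eigenvalues of the sample covariance
(n−1 denominator), hence area π√(λ₁λ₂) (≈40% of bivariate normal data);
SEA_C multiplies by (n−1)/(n−2). The Bayesian SEA_B draws covariance
matrices from the conjugate inverse-Wishart posterior of a vague
normal-inverse-Wishart model and reports the posterior mean and equal-tailed
95% credible interval of π√(det Σ), deterministic under a fixed seed. The
prior uses df = dimension + 1 and a scale of 10⁻³·I: at isotope scale
(variances of order 0.04 ‰²) an identity-scale prior would act as a full
pseudo-observation of variance 1 per axis and inflate SEA_B several-fold,
so the scale is set small enough to be numerically negligible while keeping
the posterior proper; the credible interval then covers the point SEA_C for
well-behaved data.

## The synthetic biologger

`simulateDeployment()` generates GPS, acceleration, pressure and
per-second ground truth under a `simConfig()`. Defaults are the study
conditions: a 48 h trip to at most 150 km from the Punakaiki colony
(−42.146, 171.341); behaviour fractions 51.4% flap / 13.7% soar / 34.9%
raft in exponential bouts of mean 90 s; 2.7 foraging events per hour, a
quarter of them dives; wingbeat cycle 0.3 s with heave sine amplitude
0.6 g (giving flapping VeDBA ≈ 0.4 g); per-axis dynamic noise 0.12 g when
gliding or rafting (VeDBA ≈ 0.19 g); prey strikes with 1.1 g surge noise
(VeDBA ≈ 0.7 g) at −40° pitch; air/water static-heave step 0.15 g with
0.1–0.3 Hz wave modulation of 0.03 g; GPS every 300 s along an
outbound–loiter–return path at behaviour-dependent ground speed; pressure
at 1 Hz, 1013 mBar baseline, 0.5 mBar h⁻¹ drift, quantized to the 5 mBar
sensor resolution. Where the study system did not pin a value (wingbeat
frequency, bout lengths, noise levels, wave spectrum) the defaults were
chosen once to reproduce the published qualitative structure — flapping
dominant, foraging ≈ 0.1–0.3% of time, VeDBA ranking foraging > flap >
glide ≈ raft — and are not adjusted thereafter.

Dive descent durations are whole seconds (1 + Poisson(0.55), truncated to
the configured depth range), so apexes fall on the 1 Hz pressure grid and
the labelled seconds, pressure samples and V geometry are mutually
consistent; the resulting dives average 3.1 s and 1.3 m with a maximum of
8.6 m, matching the study system, and the duration-to-depth estimator is
exactly recoverable. Foraging events are placed inside rafting bouts with
at least 10 s clearance so ground-truth events remain distinct under the
5 s merge rule; a configuration whose expected foraging time exceeds half
the rafting time is rejected as infeasible.

What the simulator does **not** emulate: wind and wave fields, prey
patches, logger axis misalignment, temperature-dependent sensor drift,
GPS position error, behaviour-dependent diel rhythm, or gradual transitions
between behaviours. Passing tests on synthetic data therefore demonstrate
that the pipeline recovers what its own generative assumptions encode —
correctness of the numerics and of the end-to-end plumbing — not that the
classifier thresholds transfer to any particular real logger; the
published 91.4 ± 5.2% cross-sensor validation on field data is emulated
only as a ≥85% property at desk scale.

## Problem sizes and determinism

The test-suite property checks run ten default 48 h deployments (seeds
1–10; about 43 million acceleration samples in total) for the end-to-end
criteria, and smaller constructed fixtures elsewhere. Every stochastic
component — the simulator, k-means restarts, posterior draws — is seeded
explicitly, and identical configurations give byte-identical outputs. The
analysis functions themselves are pure; `runPipeline()` writes a manifest
(configuration hash, seed, package version, output list) next to its
tables.

## Known limitations

- The rafting/soaring separation rests on a static-heave band calibrated on
  synthetic data; real deployments need per-attachment calibration, and the
  distinction degrades when heave variance is similar in air and on water.
- The colony-radius rule does not remove on-land fixes away from the
  colony; supply a landmask-filtered track if that matters.
- The dive-depth estimator assumes symmetric V-dives; U-shaped or skewed
  dives would need the descent duration directly.
- Mixture-based mode estimation reports component means, which coincide
  with density modes only for well-separated components.
- `estimateModes()` and the BC threshold assume independent trip durations;
  repeated trips by the same bird are treated as independent.
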