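---
title: "Methods: modeling connectivity development along the cortical hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling connectivity development along the cortical hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
models, the choices made where the design was genuinely open, and what the
synthetic validation does and does not establish about real data.

## The scientific object

The sensorimotor–association (S-A) axis assigns each cortical parcel a unique
rank from primary sensorimotor cortex (rank 1) to transmodal association
cortex (rank P). The package quantifies whether age-related change in
functional connectivity is organized along this axis: regional age effects
are estimated independently per parcel, and their spatial arrangement is then
compared to the axis with rank correlations whose significance is assessed
against spatial-autocorrelation-preserving nulls.

## Regional connectivity metrics

A subject's connectivity matrix is the Pearson correlation of concatenated,
per-run z-scored parcel timeseries. FC strength of a parcel is the mean of
its P−1 off-diagonal edges, unthresholded. Between- and within-network
connectivity split those edges by the parcel's network assignment and obey
the exact identity

    fc_strength = ((n_within − 1)·within + n_between·between) / (P − 1),

which the tests verify to 1e−12. Sensitivity variants follow the field's
usage: `absolute` averages |r|; `positive_only` averages only the strictly
positive edges, with the denominator equal to the count of positive edges
(a parcel with none is flagged missing rather than zero-filled — "include
only positive correlations" is read as dropping, not zeroing, the rest).
Correlations are averaged raw, without a Fisher z-transform, matching how FC
strength is defined in this literature. Global signal regression is offered
at the parcel level (the cross-parcel mean timecourse regressed out of every
column); it is an approximation to voxelwise GSR adequate for studying the
sign behaviour of the metric variants, not a preprocessing replacement.

## The regional age model

Each region's metric is modeled as

    y ~ s(age, k = 3) + sex + mean_fd

a penalized thin-plate regression spline in age with linear covariates,
fitted by `mgcv::gam`. REML is the default smoothness selector (GCV and
fixed penalties are options); at `k = 3` the smooth has one penalized basis
function plus an unpenalized linear null space, so as the penalty grows the
fit collapses exactly onto the ordinary linear regression — a property the
tests exploit as an oracle at both penalty extremes (unpenalized fits match
the normal equations to 1e−8; an effectively infinite penalty matches `lm()`
to 1e−6).

The age effect size is the change in adjusted R² between this model and a
reduced model with no age term, where adjusted R² uses the model's total
effective degrees of freedom. The effect's direction is the sign of the age
coefficient in the equivalent linear model; the signed effect clips negative
ΔR²adj to zero before signing (adjusted-R² differences can be slightly
negative under the null; the raw value is retained alongside).

**Significance.** The full and reduced models are compared with an F
statistic on their residual sums of squares. The numerator degrees of
freedom are fixed at the age smooth's basis dimension (k − 1); the
denominator uses the full model's effective residual degrees of freedom
(n − total edf). Using the realized edf in the numerator would let the
data-adaptive smoothness selection inflate the type-I error (we measured
~9% at a nominal 5% over 2000 null simulations); with the basis dimension it
is calibrated (5.0% over the same simulations). The acceptance suite checks
this calibration property over 500 null replicates. Multiple comparisons are
controlled with Benjamini–Hochberg FDR at Q < 0.05.

**Prediction.** Fitted trajectories hold numeric covariates at their sample
means and binary covariates at the sample proportion — the marginal age
curve. Extrapolation beyond the training age range is refused rather than
clamped. Posterior uncertainty comes from the standard Bayesian view of the
penalized fit: coefficient draws from a Gaussian centred at the estimates
with the fit's posterior covariance (conditional on the smoothing
parameter), mapped through the prediction basis.

## Axis construction

An axis is derived from a set of feature maps by ranking each map
(orientation flags make "high value" point to the association pole),
averaging ranks across maps, and re-ranking the averages into a unique
1..P ordering. Ties in the averaged ranks are broken by stable input order —
the one deterministic rule available when the source derivation is silent. A
constant map contributes the uniform mid-rank, with a warning. Rank-based
construction makes the axis invariant to monotone transforms of any input
map, and reversing every orientation reverses the axis exactly (absent
ties); both are tested properties.

## Spin-based spatial inference

Parcel-level brain maps are spatially autocorrelated, so naive permutation
nulls overstate significance. The spin test builds a null by rotating the
spherical parcel geometry: per rotation, a uniformly random rotation is
applied to left-hemisphere centroids and its x-mirrored counterpart to the
right, and each rotated centroid takes the value of the nearest original
same-hemisphere centroid (many-to-one allowed). The two-sided p-value is
(1 + #{|r_null| ≥ |r_obs|}) / (n_rot + 1), strictly positive, with floor
1/10001 ≈ 0.0001 at 10,000 rotations. By default the axis map is the one
rotated and the effect map stays fixed; either is selectable, and the
observed statistic is identical both ways.

Two geometric details matter for validity and emerged during development:

- *Which fields the null is exchangeable for.* The mirrored-rotation group
  preserves the law of fields whose cross-hemisphere covariance is computed
  after mirroring right-hemisphere coordinates through the x-plane. The
  package's smooth-map generator (`random_smooth_maps()`) and the
  parcellation's rank noise use exactly this construction; calibration
  checked with naively folded (|x|) fields instead runs at ~18–20% at a
  nominal 5%, while the invariant construction sits inside the exact
  binomial bounds. The calibration test in the acceptance suite draws its
  200 null maps from the invariant class for this reason.
- *Identity collapse on coarse lattices.* With only ~50 parcels per
  hemisphere, a random rotation occasionally lands close enough to the
  identity that every parcel maps to itself, reproducing the observed
  arrangement exactly. On a continuous surface this event has measure zero;
  on the lattice it acquires a small artificial atom of probability and
  would double-count the observed arrangement, which the p-value's +1 term
  already represents. Rotations that collapse to the exact identity
  reassignment are therefore redrawn. The effect on p-values away from the
  floor is of the order of the collapse probability (~1e-4) and immaterial;
  at the floor it removes a spurious tie.

## Age-resolved alignment

Model-predicted FC strength is evaluated on a grid of exactly 200 evenly
spaced ages spanning the cohort range (about monthly over an 18-year span).
For each of 10,000 joint posterior draws across regions, fitted values are
correlated with axis ranks at every grid age; the per-age median and
2.5/97.5 percentiles give the trajectory and its 95% credible band. Spearman
is the default correlation here and for axis alignment (Pearson is the
default only for map-vs-map comparisons between effect maps); both are
configurable since the original analyses do not pin the age-resolved method.
Ages where some draw's fitted values are constant across regions produce
missing correlations for those draws; all-missing ages stay `NA` rather than
erroring.

A caution the tests made quantitative: at an age where the true
across-region signal is weak, the median-across-draws correlation is
systematically attenuated relative to the correlation of the point-estimate
fits (fresh posterior noise shrinks a noise-driven rank correlation by about
1/√2). Endpoint agreement between the two is therefore only a reliable
property when real signal is present at both ends of the age range — which
shaped the synthetic generator's design below.

## Edge-level topography

Every unordered parcel pair's correlation is modeled with the same age model
(the reduced and linear models share one design across edges and are solved
in a single pass; the penalized fit is per edge), with FDR across all
P(P−1)/2 edges. The signed edge effects are then summarized by a
tensor-product smooth over the two endpoint ranks, `effect ~ te(rank_1,
rank_2)` with cubic-type marginal bases of dimension 5 and REML smoothness.
Symmetry is enforced by fitting each edge under both orderings of its
endpoints, which makes the fitted surface symmetric to numerical precision —
simpler and more testable than a constrained basis. No significance mask is
applied to the surface; all edges contribute. Seed-based profiles expose the
P−1 signed effects incident to one parcel.

## The synthetic cohort: what it emulates, and what it does not

Parcel timeseries follow a factor model: a cortex-wide shared factor with
subject- and parcel-specific loading, one factor per network, and white
noise. The planted developmental effect lives in the shared-factor loading,

    w_p(age) = w0 + delta_p · age / age_max,
    delta_p  = delta_max · (1 − 2·(rank_p − 1)/(P − 1)),

so the loading gradient — and with it the axis alignment of connectivity —
accumulates linearly over development from a common baseline at birth. The
cohort observes ages 5–23 (uniform; the union of the age ranges of the
developmental cohorts this design emulates), by which time differentiation
has partially accumulated and keeps strengthening: the age-resolved
alignment is already substantial at the youngest observed age and largest at
the oldest. The slope `delta_p` decreases strictly along the axis, so the
planted alignment between signed age effects and ranks is exactly −1 and
`delta_max = 0` yields an honest null cohort. Pivoting the loading at birth
rather than mid-cohort is the one generator choice that makes both tested
age-resolved properties (divergence growing with age, endpoint agreement
with point estimates) hold with margins instead of being coin flips, and it
matches the observed phenomenology of alignment rising monotonically through
youth.

Defaults: P = 100 parcels (50 per hemisphere on deterministic Fibonacci
sphere lattices, ranks from polar angle plus spatially smooth bilateral
noise), 7 networks as contiguous rank bands, n = 300 subjects, two runs
(labels "rest" and "task1") of 200 timepoints at TR 3 s, delta_max = 0.3,
w0 = u0 = 0.5, sigma = 1. Head motion is lognormal with its median falling
with age (about 0.17 mm at age 5 to 0.08 mm at 23) and inflates the noise
scale multiplicatively — exercising the motion covariate against a
realistic age confound.

What the generator does **not** emulate: hemodynamics and autocorrelated
BOLD noise, scanner/site batch effects (harmonization is treated as a
pre-applied external step), non-uniform age sampling, network-size
asymmetries, and any nonlinearity in the true developmental trajectories
(the planted change is linear in age; the GAM's job in the synthetic study
is to not invent curvature). Passing tests on this cohort therefore
establish correctness of the estimators and calibration of the inference,
not that real development is this clean.

## Quality control and the pipeline

Runs with mean framewise displacement ≥ 0.3 mm are excluded; among multiple
sessions only the one with most surviving runs is kept (ties to the earliest);
subjects with under 7 minutes of retained concatenated data are dropped. The
motion covariate is recomputed as the mean FD over retained runs only.
`run_full_pipeline()` chains QC, concatenation, connectivity, metrics,
age models with FDR, the spin test, the age-resolved analysis and optional
edge analyses, with a manifest of subject counts per exclusion stage;
identical config and seed reproduce identical outputs, including files.

## Numerical choices collected

- Per-run z-scoring before concatenation; concatenation order irrelevant
  afterwards.
- Zero-variance parcels are an error naming the parcel, not a silent NA.
- Constant responses: smoothness selection is vacuous and mgcv's REML step
  fails, so the penalty is pinned at a fixed value; the fit is flat either
  way, the direction is 0 and the p-value 1.
- Final axis re-ranking ties broken by stable input order; `ties.method =
  "first"` on the averaged ranks.
- Rotation matrices are QR-orthogonalized Gaussian matrices, sign-fixed to
  determinant +1 (Haar-uniform).
- Posterior covariance is symmetrized and checked for positive
  semidefiniteness before sampling.
- The credible-band coverage property is checked against a truth inside the
  k = 3 model family (linear plus mild quadratic, curvature 0.01 per year²):
  pointwise coverage of a penalized smooth's credible band is a statement
  under correct specification, and a truth outside the basis span measures
  approximation bias instead (a deliberately wiggly truth drives coverage
  to ~24% with perfectly healthy code).

## Problem sizes in the shipped checks

The test suite runs the planted and null studies at the default study
conditions (P = 100, n = 300), spin calibration with 200 smooth null maps at
500 rotations, type-I calibration with 500 null model fits, coverage with
200 simulated fits at 10,000 posterior draws, the p-floor at 10,000
rotations on a 1000-parcel lattice, and the full edge analysis (4,950 edge
fits); smaller lattices and cohorts are used where only mechanics are being
exercised. The acceptance script re-runs the same study end to end under a
caller-supplied seed.

## Known limitations

Cross-sectional only — no within-person trajectories or random effects; no
site/batch modeling (harmonize upstream); parcel-level GSR is a stand-in for
voxelwise practice; the spin test's nearest-centroid reassignment is
many-to-one, so a rotated map's value multiset is only approximately
preserved on coarse lattices; Pearson correlation as the connectivity
measure inherits its usual insensitivity to nonlinear coupling.
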