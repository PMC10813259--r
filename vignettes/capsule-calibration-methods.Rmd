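---
title: "Methods: reduced-order hip capsule mechanics and instantaneous surrogate calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order hip capsule mechanics and instantaneous surrogate calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsulereg)
```

# The modeling problem

After total hip arthroplasty the capsule — the ligamentous sleeve from the
acetabular rim to the femoral intertrochanteric line — is the main soft-tissue
restraint against dislocation. Capsule models useful for surgical planning
must be subject-specific, but calibrating a capsule model against a subject's
measured torque–rotation laxity by optimization takes hours to days.
`capsulereg` implements the alternative: learn, once, a statistical map from
*observable* quantities (hip laxity and attachment-site geometry) back to the
capsule's mechanical parameters, so that calibration of a new subject becomes
a single regression evaluation.

The package has four interlocking parts:

1. a **reduced-order capsule simulator** — six circumferential sectors of
   nonlinear tension-only path-springs wrapping the prosthetic femoral head,
   solved for quasi-static torque–rotation equilibrium;
2. a **statistical shape model (SSM)** of the paired attachment ellipses,
   fitted by PCA on corresponded node loops;
3. a **probabilistic sampler** that draws capsule parameters and shape scores
   by Latin hypercube sampling and simulates each draw into a 40-metric
   laxity profile;
4. a **stepwise multilinear regression surrogate** predicting the twelve
   mechanical parameters from a laxity subset plus four shape scores, with a
   closed-loop validation harness (predict, re-simulate, RMSE).

# The capsule model

## Geometry

Both attachment sites are planar ellipses, resampled into `n` nodes at equal
arc length (`resample_ellipse()`), starting at the most superior point of
each loop and traversed counter-clockwise as seen from lateral, so that node
`i` on the acetabular loop corresponds anatomically to node `i` on the
femoral loop. The capsule mesh (`build_capsule_mesh()`) connects corresponded
nodes with `n_lines` longitudinal lines (default 36, i.e. one line per 10° of
circumference), assigned to six equal contiguous sectors numbered from the
most superior line. The sectors approximate the named capsular ligaments;
each carries an independent total stiffness (N/mm) and pre-strain
(dimensionless) — the twelve mechanical parameters.

Lines wrap the femoral head, modeled as a sphere of radius 22 mm (the scale
of a dual-mobility liner) centered at the hip rotation center. The shortest
admissible path is the straight chord when it clears the sphere and the
tangent–arc–tangent geodesic otherwise (`wrapped_length()`). Because the
sphere is centered at the rotation center, wrap contact forces are radial
and contribute no moment about the joint — the torque of a line reduces to
the moment of its insertion-point tension along the departing tangent.

## Springs

Each line is a single path-spring with the piecewise toe-linear ligament
law (`spring_force()`): zero force in compression, a quadratic toe
`f = k δ²/(4 δ_t)` up to `δ = 2 δ_t`, then linear `f = k (δ − δ_t)`, with
continuous value and slope at the junction. The toe elongation is
`δ_t = 0.03 L₀` — a conventional ~3% toe strain for capsular tissue. A
sector's stiffness is divided evenly across its parallel lines; series
subdivision along a line is collapsed into the single path-spring, which is
mechanically equivalent for uniform per-line properties in a quasi-static
tension-only model.

## Pre-strain semantics

The slack length of a line is defined as

`L₀ = reference_length / pre_strain`,

where the reference length is the as-meshed wrapped length at neutral.
Pre-strain above one therefore means the line is taut at neutral; below one,
slack. This convention makes laxity monotone non-increasing in each sector's
pre-strain and reproduces the expected sector ordering: the superior sector
(≈ iliofemoral ligament, pre-strain 0.99) is nearly engaged at neutral while
the inferior sectors (pre-strain ≈ 0.5–0.7) fold slack and engage only near
the end range. Competing conventions (pre-strain as an engineering strain,
or as the slack-to-reference ratio) would put every sector tens of percent
beyond yield at neutral for the same parameter table, which is not
physically tenable; the chosen mapping is the one declared throughout and is
a package design decision, since reduced-order spring sleeves admit several
self-consistent definitions.

## Pose and equilibrium

Hip orientation follows a three-cylindric open chain applied intrinsically:
flexion about the medial-lateral axis, then ab/adduction about the rotated
anterior-posterior axis, then internal/external rotation about the rotated
superior-inferior axis. During an isolated-torque test the unloaded rotation
DOFs are held at neutral (the fixed-neutral choice; a free-DOF equilibrium
would require a 3-DOF solve the torque data cannot constrain).

A laxity value is the rotation at which the capsule's restoring torque about
the loaded axis balances the applied torque. The torque-rotation curve is
evaluated exactly (no linearization) and the root is found by marching the
bracket outward in fixed 5° steps — so a crossing under a local torque peak
cannot be stepped over — followed by bisection to an interval below 1e-3°.
Targets unreachable within ±175° raise an explicit non-convergence error;
they are never clipped. Equilibria can be slightly negative when the capsule
is taut at neutral; the sign convention is positive in the loaded direction.
The full profile (`evaluate_laxity_profile()`) solves 4 directions × 5
flexion angles (0/30/45/60/90°) and records rotations at 1 N·m (the
slack-to-stiff transition) and 5 N·m: 40 metrics from 20 solves.

# Statistical shape model

`fit_shape_model()` performs mean-centered PCA on the flattened coordinates
of the concatenated acetabular + femoral loops. No Procrustes alignment is
applied beyond the anatomic-frame convention (hip center at the origin),
mirroring how attachment geometry would be expressed after image-based
anatomical alignment. Mode standard deviations are the sample SDs of the
training scores, and all scores are expressed in SD units, so a score of +2
is the "+2 SD" shape; this makes the ±2.0 sampling bounds on the shape
scores directly interpretable as 95% truncation bounds. Whether scores
should be raw (mm-scaled) or standardized is genuinely open in this kind of
pipeline; SD units were chosen because they make the sampling table and the
reconstruction figures self-consistent, and the regression is invariant to
the choice up to coefficient rescaling. Four modes are retained by default.

# Probabilistic sampling

The sixteen inputs are the twelve mechanical parameters plus four shape
scores. Each is sampled from a truncated normal covering 95% of the
population: stratified uniforms on `[Φ(−t), Φ(t)]` (t = 1.96 SD for the
mechanical parameters; t = 2.0 for the shape scores, reading their "±2.0"
range as the truncation bound) mapped through the normal quantile function,
with one sample per equal-probability bin per marginal and randomized
pairing across columns (Latin hypercube). The default means and SDs are the
package's input registry (`default_distributions()`).

`generate_trial_dataset()` simulates each sampled row into its 40-metric
profile. Trials are deterministic given the seed; a failed equilibrium flags
the trial rather than silently dropping it.

# Surrogate regression

For each of the twelve outputs, `capsule_surrogate()` runs forward–backward
stepwise selection over linear terms: the candidate with the smallest
partial-F p-value enters while below `p_enter = 0.05`, the included term
with the largest p-value leaves while above `p_remove = 0.10`, until no move
changes the model (the classic stepwise-lm defaults). Candidates are the
training set's laxity metrics — Sets 1–9 in the registry, from the full
I-E + Ad-Ab × {0, 30, 60, 90}° set (N = 32) down to I-E × {0, 90}° (N = 8) —
plus the four shape scores. Twelve independent per-output fits are used
rather than one multivariate fit with shared selection, because the outputs
have quite different signal-to-noise (taut-sector parameters are far better
determined than slack-sector ones) and per-output selection lets each
equation keep only what it can support. An intercept is always included:
without one a linear form cannot represent the nonzero parameter means at
zero laxity offset. Laxity predictors stay in raw degrees and scores in SD
units; mixed scaling is immaterial for least squares.

Prediction (`predict()`, `predict_parameters()`) is a dot product per
output — milliseconds. Before re-simulation, raw regression output is
clipped to the observed training range of each output: a linear surrogate
has no support outside the sampled population, and unclipped extrapolations
(e.g. a negative stiffness from a noisy laxity measurement) can be
physically meaningless or unsimulatable. The diagnostic path that re-feeds
known true parameters bypasses this guard.

# Closed-loop validation

`closed_loop_validate()` scores a surrogate the way it will be used: predict
parameters from a trial's laxity subset and true shape scores, rebuild the
mesh from those scores, re-simulate all 40 metrics, and compare against the
trial's original laxities. Per-trial RMSE is always computed over all 40
metrics regardless of the training subset, so reduced training sets are
penalized for what they fail to constrain. The convergence study trains on
nested subsets (100–450 trials by default, nesting for variance reduction)
against a fixed 50-trial holdout and declares convergence when the last
relative RMSE change is below 5%. Between-set differences use two-sided
Student's t-tests with equal-variance pooling on the per-trial RMSE samples;
the tests are unpaired as named, though the shared holdout would also
justify a paired variant.

# The synthetic study population

No anatomical database ships with the package; the synthetic generator
(`synthetic_attachment_population()`) defines the study conditions. Its base
geometry is a plausible implanted right hip built from anatomical scale
constraints — rim and intertrochanteric ellipses of ~23–35 mm semi-axes
around a 22 mm head — refined so that the resulting capsule behaves like a
functional joint across the whole sampled parameter space: every one of the
20 isolated-torque poses reaches 5 N·m with margin (worst-corner parameter
draws included), and mean-parameter laxities stay within a physiological
envelope (≤ ~50° at 5 N·m). Four orthogonal displacement modes mimic the
dominant anatomical modes reported for hip SSMs — capsule length, femoral
A-P shift (version), femoral S-I shift (inclination), acetabular depth —
with SDs of 4, 3, 2, 1 mm and 0.05 mm isotropic node jitter, leaving the
four modes carrying ≈ 85% of total shape variance, the dominance structure
expected of attachment-site SSMs. Synthetic "specimens"
(`synthetic_specimen()`) emit only the experimentally measurable I-E subset
(16 values) plus true shape scores, with 1.0° default measurement noise
(plausible motion-capture laxity repeatability).

What the generator does *not* emulate: real bone meshes and their
segmentation error, non-elliptical attachment footprints, implant
malposition, and bone-on-implant contact outside the capsule. Passing the
closed-loop tests therefore demonstrates that the calibration machinery is
self-consistent and near-linear over the sampled space — not that the
simulator reproduces any particular cadaver's laxity magnitudes.

# Numerical choices and problem sizes

* Ellipse fitting: plane by SVD, then the numerically stabilized direct
  least-squares conic fit constrained to ellipses; degenerate inputs
  (< 6 points, collinear, non-elliptical conic) raise errors.
* Arc-length resampling uses a dense cumulative-chord table (≥ 20,000
  segments), giving equal spacing to ~1e-6 of the perimeter.
* Superior-point ties are broken by largest anterior coordinate, then
  lowest index.
* Bisection tolerance 1e-3°, bracket march 5°, search limit ±175°.
* The package's own experiments use 500 trials at 36 lines (a ~3-minute
  dataset on one core), a 450/50 split, and 100-subject shape populations;
  the regression and validation layers are tested additionally on 80-trial
  datasets and 12-line meshes where full scale adds nothing.

# Known limitations

* Laxity magnitudes are engine-specific: a reduced-order spring sleeve has
  no membrane shear, no contact outside the head sphere, and no friction,
  so absolute rotations are not comparable to finite element or cadaver
  values — only the calibration loop built on top of them is.
* Slack sectors (pre-strain ≤ ~0.7) engage only at end range; their
  stiffness is weakly identifiable from laxity, and the surrogate predicts
  them near the population mean. The closed loop is insensitive to this by
  construction, but downstream uses that depend on slack-sector stiffness
  should not rely on the regressed values.
* The SSM is linear; strongly nonlinear shape families (e.g. dysplastic
  morphologies) are outside its span.
* Fixed-neutral unloaded DOFs slightly overestimate restraint compared to a
  free equilibrium.
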