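---
title: "Methods: near-wall hemodynamic quantification in anewall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: near-wall hemodynamic quantification in anewall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`anewall` implements a quantification chain for 4D phase-contrast MRI
(PC-MRI) of intracranial aneurysms. PC-MRI encodes each velocity
component into the phase of the complex MR signal: a speed equal to the
velocity-encoding limit (VENC) maps to a phase of ±π, beyond which the
measurement aliases (wraps) by multiples of 2·VENC. The chain takes a
gridded, time-resolved, three-component velocity field plus a
triangulated lumen surface, and produces validated flow rates, wall shear
stress (WSS) vectors over the cardiac cycle, their time average (TAWSS),
the oscillatory shear index (OSI), sac morphometrics and image-quality
metrics.

For a Newtonian fluid the Cauchy stress is σ = −pI + 2μD. Projecting the
traction σn tangentially at a no-slip wall removes the pressure and the
tangential derivatives of the normal velocity component, leaving

WSS = μ (∂v_t1/∂n, ∂v_t2/∂n, 0)

in the local orthonormal basis {t1, t2, n}. Everything else in the WSS
module is the numerical estimation of those two wall-normal derivatives.

## The synthetic study conditions

No scanner data ship with the package; a synthetic module generates the
emulated acquisition with known ground truth. Its defaults are fixed and
define the conditions every test runs under:

* grid: cell-centred, right-handed, physical millimetres, 0.5 mm
  isotropic voxels; axis order (x, y, z, component, phase);
* timing: 21 cardiac phases at 49 ms (the sampled cycle overcovers a 1 s
  pulse by 2.9%, as acquired with a prospective 1 Hz trigger);
* VENC 1.1 m/s (1.2 m/s for the wider-vessel case);
* fluid: glycerine/water blood analogue, ρ = 1142 kg/m³,
  ν = 4.67·10⁻⁶ m²/s, so μ = ρν = 5.33·10⁻³ Pa·s;
* inlet flow: a fixed 8-harmonic single-peak carotid-like pulse shape,
  rescaled to a prescribed mean (default 4.38 ml/s). The harmonic table
  is a built-in generic shape — the study's exact inlet waveform is not
  tabulated anywhere, so only its mean, 1 Hz period and qualitative
  single-systolic-peak character (peak/mean ≈ 1.8, within the
  physiological 1.4–2.0 band) are emulated;
* noise: magnitude images are a constant lumen signal A (background
  A/10) plus Gaussian noise of σ = A/SNR; each velocity component
  receives matched phase noise with σ_v = (√2/π)·VENC/SNR, the standard
  PC-MRI relation that makes the velocity-to-noise ratio
  self-consistent; target SNR defaults to 120, inside the 100–150 range
  of the emulated acquisitions. Noise is added in image space: no
  k-space simulation, coil sensitivities or compressed-sensing
  artefacts.

Analytic fields are axial flows in a straight tube: the steady Poiseuille
parabola, and the oscillatory pipe-flow (Womersley) solution built per
harmonic from Bessel functions J₀, J₁ of complex argument, superposed
with the steady term. Both carry closed-form ground truth (flow waveform
and wall shear time series). Base R's `besselJ` is real-only and no
installed package evaluates J at complex argument, so the package
evaluates the ascending power series for |z| ≤ 14 and Gauss–Legendre
quadrature of the integral representation beyond; both branches are
cross-checked in the tests against `besselJ` on the real axis and
`besselI` on the imaginary axis.

What the phantoms do *not* emulate: curved or branching parent arteries
carrying flow, intra-sac recirculation (the sphere-on-tube sac is a
dead-flow cavity), background phase errors, segmentation error beyond
mesh discretisation. Passing tests therefore demonstrate correctness of
the estimators against analytic truth and self-consistency of the chain,
not robustness to anatomical complexity.

## Conventions the literature leaves open

Several quantities have no universally fixed operational definition;
the package fixes them as follows.

* **Diastolic baseline** for temporal unwrapping: the cardiac phase with
  minimum spatial-mean speed inside the lumen mask. Walking forward
  cyclically from it, a step beyond +VENC subtracts 2·VENC from all
  subsequent samples (and conversely). The method assumes the baseline
  phase itself is alias-free and that true inter-phase steps stay below
  VENC; super-VENC steps remaining after correction are reported as
  unresolved rather than silently altered.
* **Normalized-median test**: 8-connected in-plane neighbours in the
  slice orthogonal to the dominant flow axis (largest mean absolute
  component; configurable), detection threshold 1, noise floor
  ε = 0.05·VENC, flagged voxels replaced by the component-wise
  neighbourhood median, voxels with fewer than 3 valid neighbours left
  untouched and listed.
* **Sac isolation**: triangles whose centroid lies within
  (D_vessel + 1 mm)/2 of the nearest centerline point are removed;
  "within a diameter D_vessel + 1 mm around the centerline" is read as a
  diameter, halved for the removal radius, for dimensional consistency.
  The sac is the largest remaining connected component (others
  retrievable by rank).
* **Neck plane**: total least squares — the plane through the neck-loop
  centroid whose normal is the smallest principal axis; this minimises
  the summed squared orthogonal distances, and the tests verify
  equivalence with a brute-force orientation search.
* **Morphometrics**: perpendicular height is the maximum signed distance
  of sac vertices from the neck plane (sac side); maximum height the
  largest distance from the neck-loop centroid to a sac vertex; maximum
  width the largest pairwise distance of sac vertices projected onto the
  neck plane; neck diameter the area-equivalent diameter 2√(A/π) of the
  projected neck loop; volume by the divergence theorem after closing
  the sac with a planar neck fan; aspect ratio = perpendicular height /
  neck diameter. With these conventions the two carotid-ophthalmic
  reference cases reproduce their published aspect ratios (1.24, 1.35);
  the middle-cerebral case does not (6.99/11.62 ≈ 0.60 vs the published
  0.88, which no simple height/neck convention reproduces from the other
  published numbers) — the discrepancy is left standing rather than
  forced.
* **Systole**: the phase index of the maximum inter-plane mean flow
  rate; used for the per-phase WSS summary statistics.
* **SNR phase pair**: consecutive phases whose masked mean speeds differ
  by ≤ 1.0%; among qualifying pairs the one with the highest
  difference-method SNR (lowest index on ties); the minimum-difference
  pair with a warning when none qualify.
* **Undefined OSI** (zero shear over the whole cycle) is reported as
  missing, not 0 or 0.5, to avoid fabricating extremes at dead-flow
  vertices.

## Numerical choices

* **WSS normal-line interpolant**: 4 samples over 1.5 mm with the wall
  sample pinned to zero; the unique cubic interpolant reproduces
  polynomial profiles up to degree 3 exactly, so the Poiseuille parabola
  is differentiated exactly up to velocity-interpolation error. Wall
  normals come from a PCA of the 20 nearest wall points, oriented into
  the lumen by probing the interpolated mask; on sparse clouds the PCA
  normal tilts with patch curvature, so subsampled evaluations keep the
  full cloud for the normal estimate (`eval_subset`).
* **Flow integration**: the normal velocity component is interpolated
  onto a 0.1 mm in-plane raster; boundary pixels get fractional weights
  from a 4× supersampled point-in-contour test against the
  surface–plane intersection polygon (the partial-volume correction).
* **Time quadrature** for TAWSS/OSI: rectangle rule on the uniform
  phase grid, cycle treated as periodic — exact for the sampled
  harmonics of the generator.
* **Centerline**: voxelised interior (0.4 mm), distance-to-wall per
  voxel, shortest path under cost length/(distance + 0.05 mm) on the
  26-connected graph, spline smoothing, then per-point re-centring on
  the maximal-inscribed-sphere ridge (a 2-D local maximisation of wall
  distance orthogonal to the tangent) to remove voxel quantisation, and
  a final light re-smooth. D_vessel is twice the wall distance at the
  refined points.
* **Registration**: BFGS (quasi-Newton) on 3 Euler angles + 3
  translations, maximising the mean reference-image intensity over
  interior sample points on a 0.3 mm lattice, numeric gradients,
  flat-objective detection for featureless references.
* **Containment**: +z ray-casting with a ~10⁻⁷ mm ray nudge so
  lattice-aligned mesh edges are counted once; containment within that
  distance of the surface is indeterminate by construction, and tests
  compare against signed-distance oracles away from the surface shell.
* **Degenerate inputs**: non-watertight surfaces are rejected for
  masking; phantom unions that are deliberately unstitched (tube + sac
  cap) may bypass the check where ray parity remains well defined;
  empty sacs return an explicit status; more than 20% unusable wall
  vertices aborts the WSS stage as a geometry/registration failure.

## Known limitations

* The threshold-1 normalized-median repair, applied to steep parabolic
  profiles sampled at 0.5 mm, systematically flags near-wall voxels
  (their one-sided neighbourhoods make the local median sit deeper in
  the profile) and lifts their velocities towards the interior median.
  On the synthetic tube this inflates integrated flow by ~10–15%
  end-to-end, while the same stage on analytic noise matches its
  brute-force definition voxel-for-voxel. This is a property of the
  published parameterisation at acquisition resolution, not of the
  implementation; the end-to-end test asserts the realistic chain
  accuracy, the unit tests the analytic one.
* Temporal unwrapping cannot recover aliasing present at the diastolic
  baseline itself, nor true inter-phase steps above VENC; both are
  inherent to the single-threshold walking scheme.
* WSS magnitudes are biased low at acquisition resolution (−3% at
  0.5 mm on the tube phantom) and rise monotonically with grid
  refinement — consistent with the general observation that PC-MRI WSS
  estimates increase with spatial resolution.
* The dead-flow sac phantom yields near-zero WSS with noise-dominated
  direction, so its OSI approaches 0.5; this mirrors the caveat that
  high OSI in low-SNR, low-velocity regions can be noise-induced.

## Problem sizes in the shipped tests

The suite runs analytic fields at 0.1–0.5 mm on 6–20 mm tubes, wall
clouds of a few hundred vertices, a 16³ grid for the brute-force
outlier-test oracle, 100 seeded replicates for the SNR estimator and two
full end-to-end cases; these sizes keep the whole suite under a few
minutes on one CPU while leaving every tolerance at the value stated by
the corresponding analytic argument.
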