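---
title: "Annulus biomechanics and AVB risk after TAVR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annulus biomechanics and AVB risk after TAVR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavrisk)
```

## The problem

Transcatheter aortic valve replacement (TAVR) anchors a stented prosthesis
by oversizing it against the aortic annulus. The atrioventricular (AV)
bundle enters the ventricular septum beneath the interleaflet triangle
between the non-coronary and right-coronary cusps; calcium deposits pressed
against this *conduction system zone* by the expanding frame can produce
atrioventricular block (AVB) and force permanent pacemaker implantation.
`tavrisk` implements a pipeline that (i) simulates the mechanical state of
the annulus after deployment, (ii) learns the relation between
conduction-zone stress, clinical factors and the AVB outcome, and
(iii) inverts that relation to propose a valve size and a cylindrical-sector
*vacancy angle* θ — a sector cut from the frame over the conduction zone —
that keep the predicted risk acceptable.

Real patient imaging is not distributable, so the package ships a seeded
synthetic cohort generator that emulates the reference cohort's published
marginals; every stage of the pipeline is exercised and tested against it.

## Virtual calcium remodelling

Deposits are measured (in the emulation: generated) on the native valve in
cylindrical coordinates. Deployment is assumed to press each deposit onto
the aortic wall:

* a **regular** deposit is a slab of thickness *d* that slides along the
  radial line through its centre until its outer face touches the wall,
  i.e. its centre lands at radius `a − d/2` for inner wall radius `a`;
* an **irregular** deposit is a rigid rod between two endpoints that
  realigns until *both* endpoints contact the wall. A pure rotation about
  a centroid held at `a − d/2` can achieve two-point contact only at one
  special chord length, so the implemented motion is the composition of a
  rotation about the vertical axis through the endpoint midpoint (the
  smallest angle turning the chord perpendicular to its radial line) and a
  radial slide placing the midpoint at `sqrt(a² − ℓ²)` (ℓ the planar
  half-chord). This is closed-form, exact, idempotent, and mirror-
  symmetric; a brute-force angle × slide search is the test oracle.

Volumes, lengths and thicknesses are conserved exactly. Remodelled
deposits may overlap; overlaps are resolved only through the angular
thickness profile `d(φ)`, which records the per-sector **maximum** deposit
thickness — a stack pressed by a rigid frame cannot protrude further than
its thickest member (a sum rule would double-count).

## The annulus elasticity model

The annulus wall is a cylindrical shell (inner radius `C_annu/2π`, default
wall 2.5 mm, height 10 mm) meshed as a circumferentially periodic
structured grid of eight-node hexahedra. The default resolution, 92 × 17
× 5 = 7,820 elements, reproduces the documented element count; node
ordering is angle-major, then axial, then radial, so stress features align
across patients.

Tissue is homogeneous, isotropic and linearly elastic. Because the native
leaflets are crushed against the root, the constants are volume-fraction
blends of the two published rows (root: E = 2 MPa, ν = 0.45,
2000 kg/m³; valve: E = 8 MPa, ν = 0.45, 1100 kg/m³):
`E = E_valve (1 − P_root) + E_root P_root`, and likewise for ν and density.

Deployment is modelled as a **displacement** boundary condition: stent
expansion is kinematically controlled once the frame is fully open, which
also keeps the discrete problem well-posed. Every inner-surface node
outside the vacant sector is prescribed the radial displacement
`u(φ) = max(0, R − a) + d(φ)` with `R` the valve radius (nominal size is a
diameter; it is differenced against an annulus *radius*, hence
`R = size/2`). Nodes inside the open sector `(−θ/2, +θ/2)` carry no
prescription — the cut frame does not push there. The two axial end rings
are held axially (`u_z = 0`); together with the three-component
prescription at the inner nodes this removes all rigid modes, and it makes
the uniform-oversize case exactly plane strain, so the thick-walled
cylinder (Lamé) solution is the verification oracle (agreement within 5%
at the default resolution, improving under refinement; the residual
discrepancy is the quadrature-to-node stress recovery offset of half a
radial element).

The solver assembles hex8 stiffness with 2 × 2 × 2 Gauss quadrature, once
per distinct element geometry (periodicity makes elements identical across
axial layers), and factorises the constrained system with a sparse
Cholesky decomposition. Stress tensors are recovered as element means of
the quadrature points and averaged to nodes — the simplest defensible
recovery; the von Mises equivalent is the per-node scalar. Displacements
are independent of E under displacement control, so the stiffness is
assembled at unit modulus and stresses scaled by E afterwards. For the
design search, the solution's linearity in the prescribed magnitudes is
exploited: per vacancy angle, two basis solves (unit uniform oversize; the
calcium profile alone) span every candidate size.

The scalar loading force `F = K (R − C_annu/2π + d)` uses the wall
stiffness `K` (default 10 N/mm — a placeholder, as no published
force-displacement regression is available) and the maximum remodelled
thickness as `d`; the angular profile `d(φ)` drives the boundary
condition instead. `F` is reported with designs and inverts exactly to a
size via `force_to_size()`.

## Features and the risk model

The feature vector concatenates the ordered von Mises stresses at
inner-surface nodes of the conduction zone — the open 90° sector about the
NCC–RCC commissure intersected with an axial band of 4 mm above the
annulus plane (no canonical height exists for this zone; 4 mm covers the
membranous septum at this scale) — with the calcified volume and the
encoded clinical
factors: sex, BMI, blood pressures, LVEF, four binary comorbidities, and
two calcium "location/distribution" encodings chosen here because no
published definition exists: the fraction of calcified volume inside the
conduction-zone sector, and the angular entropy of deposit placement over
twelve 30° sectors. The AV-bundle radius (0.6 mm) is carried as a
configuration constant.

Features are ranked by the **DX score** `|μ₁ − μ₀| / (s₁ + s₀)` (class
means and standard deviations) — no closed-form definition of this score
is published, so the standard signal-to-noise form is an explicit,
documented assumption — and the top 16 are kept; the *impact percentage*
is the selected share of the total score mass. Selected features are
z-scored on training data only.

The risk model is linear support vector regression `g(x) = ⟨w, x⟩ + b`
fitted to the binary outcome, using the **squared** ε-insensitive loss
(ε = 0.01 by default) with a ridge penalty λ — exactly ridge regression
(an L2 misfit) at ε = 0, while retaining the insensitive tube otherwise,
which is why this loss was chosen. The solver is an exact active-set
Newton iteration on this piecewise-quadratic convex objective (each step
solves the shifted ridge normal equations for the points outside the
tube); a stable active set certifies the global optimum and the final
gradient norm is stored. λ defaults to an inner 5-fold cross-validation
over `10^(-3..2)` with a fixed fold seed. Predicted risk is the linear
score clipped to [0, 1]; AVB is called above the threshold τ = 0.5.
Training always uses θ = 0 — the complete valve.

## Inverse valve design

The design space is the four nominal CoreValve sizes {23, 26, 29, 31} mm
crossed with vacancy angles 0–15° in 1° steps (the observed range is
0–12°; the ceiling is configurable). The search is exhaustive — the grid
is tiny and exactness beats cleverness — with the forward pipeline
evaluated at every point.

Reading the inverse problem as "drive predicted risk to zero" degenerates:
risk decreases monotonically with θ (vacant nodes are unloaded) and with
smaller valves, so the argmin would always be the largest cut and the
smallest prosthesis, which contradicts the clinical pattern in which most
low-risk patients receive an unmodified, conventionally oversized valve.
The implemented objective is therefore **minimal sufficient
modification**: among grid points with predicted risk at or below the
target (default τ), choose the smallest θ, then the size closest to 1.15 ×
annulus diameter (the conventional oversizing ratio); when no point is
feasible, fall back to the risk minimum under the same tie-breaks. This
yields the clinically expected behaviour — θ* = 0 at near-applied sizes
for low-risk patients, θ* > 0 with a strictly lower risk for high-risk
ones.

## Evaluation harness

Leave-one-out cross-validation refits the entire model — normalisation,
DX selection, SVR — inside every training fold; the held-out risks are
pooled for the ROC curve (trapezoidal AUC, cross-checked against pROC).
Accuracy is reported overall and per outcome group. Baselines (logistic
regression, a depth-3 decision tree, a one-hidden-layer 16-unit neural
network with fixed seeds) and the three feature-group ablation regimes run
under the identical protocol on identically selected features. A
degenerate training fold (fewer than two patients of a class) skips DX
selection with a warning.

## Sensitivity analysis

Each model factor is perturbed multiplicatively by 25 seeded uniform draws
in ±5%; the *same* draw sequence is applied to every factor so that
factors are compared at identical perturbation magnitudes. Variation is
the maximum change of predicted risk across draws and patients, in
percentage points of risk (risk is already a 0–1 percentage; a
relative-to-value measure diverges at clipped risks of 0). Factor
semantics follow the displacement-driven pipeline: `F` scales the
prescribed displacement and `E` scales stress at fixed displacement, so
the two rescale the stress block *identically* — an exact identity of this
formulation that the test suite asserts rather than hides; ν acts through
a per-patient finite difference of the forward solve (relative step 0.02);
`A` enters as force-bearing area (stress ∝ 1/A); the calcified volume,
the individual stress features and the fitted coefficients are perturbed
directly. On the default seeded cohort the material factors (ν ≈ 2%) sit
below the load-side factors (F, A ≈ 4–5%) and the overall maximum stays
within the 5-point stability bound.

## The synthetic cohort generator

The generator reproduces the reference cohort's published margins: n = 48
with 28 male / 20 female and 28 no-AVB / 20 AVB **by quota** (proportional
at other n) — a Bernoulli draw would only match in expectation; age
truncated-normal mean 79 on [71, 88]; BMI mean 29.3 on [21.3, 42.5];
deposit thickness truncated-normal mean 3.2 mm, sd 1.2 mm on (0.5, 6.8]
(the sd is unpublished; 1.2 mm makes the observed 6.8 mm maximum plausibly
reachable at cohort scale); 2–6 deposits per patient with volumes scaled
so per-patient totals span 318–683 mm³; annulus diameters normal around
24 mm; NCC/RCC deposits placed within ±60° of the commissure and LCC
deposits outside, encoding the observation that NCC/RCC calcium drives
pacemaker risk. Blood pressures and LVEF use conventional clinical ranges
(no distributions are published), and binary comorbidity prevalences
default to 0.3. Truncated normals are sampled by inverse-CDF, so a seed
fixes the cohort byte-for-byte.

Ground-truth labels come from a linear score on the *same forward
physics* the pipeline uses — the mean conduction-zone von Mises stress at
the applied size and θ = 0 — plus the conduction-zone calcium fraction,
calcified volume and clinical terms, with logistic noise; labels are the
quota-ranked noisy scores. The coefficients are set so that the signal is
essentially representable within the 16 selectable features; with signal
spread across more groups than the selector retains, recovery would be
capped by construction rather than measured. Because the per-node zone
stresses are strongly collinear across patients (a common oversize +
thickness load factor), coordinate-wise comparison of a 16-sparse fitted
weight vector with the dense truth is not identifiable; recovery is
therefore measured as the cosine (Pearson correlation) between the fitted
linear score and the noiseless generative score over the cohort, which is
the estimable meaning of "recovering the weight direction". At n = 400
and noise 0.05 the pipeline reaches ≈ 0.97.

What the generator does **not** emulate: CT intensities and segmentation,
patient-specific root anatomy beyond a parametric cylinder, hyperelastic
or anisotropic tissue behaviour, deposit fracture and contact mechanics,
and any real correlation structure among clinical covariates. Passing
tests therefore certify the pipeline's internal correctness and
recoverability under its own generative assumptions — not clinical
performance; the published real-cohort accuracies and AUCs are
deliberately out of scope.

## Numerical choices and problem sizes

Tolerances: FEM relative residual < 1e-8 (direct solve reaches ~1e-14);
wall-contact checks at 1e-6 mm; force/size round trip exact to 1e-9 mm;
SVR gradient norm < 1e-8. Ties break deterministically everywhere:
DX ranks by feature index, size snapping toward the smaller size, vacancy
ties toward θ = 0. Degenerate inputs (single-class cohorts, n < 2,
deposits thicker than the lumen, chords longer than the wall diameter,
θ ≥ 360°, non-positive material constants) raise explicit errors.

The shipped analyses use the default 7,820-element mesh for the 48-patient
cohort, the ten-patient design batch and the sensitivity study, and a
coarse 24 × 6 × 2 mesh for the n = 400 recovery study — the recovery
property concerns the statistical pipeline, not mesh convergence, and the
generator's truth uses the same resolution as the fit, so the comparison
is internally consistent at any resolution.

## Known limitations

* The cylinder-shell annulus ignores root curvature, leaflet geometry and
  the sinuses; stresses are comparative features, not absolute predictions.
* Linear elasticity at oversize-level strains is a deliberate modelling
  convention; hyperelastic behaviour would change stress magnitudes (less
  so their ranking across patients).
* The wall stiffness K is a placeholder constant; only ratios of loading
  forces are meaningful until K is calibrated.
* The vacancy angle is evaluated purely mechanically; frame integrity and
  paravalvular leak through the cut sector are out of scope.
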