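---
title: "Patient-specific volume conduction in the electrically stimulated cochlea: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific volume conduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cochleavc` models the quasi-static voltage distribution produced by a
cochlear-implant electrode inside a patient-specific cochlea, validates the
predictions against intra-cochlear back-telemetry voltage matrices, and
couples the field to a stochastic auditory-nerve population. This vignette
is the package's account of the science: the models, their assumptions, the
parameters that matter, the numerical choices, and the limitations a user
should keep in mind.

## The anatomical model

A cochlea is summarized by three scalars measured on a preoperative CBCT
scan: the largest basal diameter through the modiolar axis `A` (round-window
rim A1 to the opposite lateral wall A2), the perpendicular basal diameter
`B`, and the height `H` from the basal-turn modiolar center to the
helicotrema. The template ("non-patient-specific") cochlea has
`A = 10.083`, `B = 7.679`, `H = 7.427` mm; a patient model is the template
scaled anisotropically by `k1 = A/10.083` along x, `k2 = B/7.679` along y
and `k3 = H/7.427` along z. The template height is conspicuously larger
than any measured patient height (max 5.27 mm in the shipped cohort table);
this is taken as given and means `k3` is always well below 1 for realistic
patients.

The exact cross-sectional shapes of the original histology-derived CAD
model are not published, so the package ships its own canonical template
(`build_template()`), a fixture with these properties:

* the lateral-wall (outer duct) radius follows a log-spiral
  `R0 exp(-lambda * theta)` whose two constants are fixed analytically so
  the unscaled basal diameters are exactly `A` and `B`;
* the duct sweeps 810 degrees of insertion angle; cross-sections are
  axis-aligned rectangle stacks (scala tympani, basilar membrane, scala
  media, Reissner membrane, scala vestibuli) whose width and height decay
  exponentially from 1.7 x 1.9 mm at the base, so the scala-tympani area is
  non-increasing toward the apex;
* primary control sections sit every 180 degrees; the intermediate
  sections (90, 270, ..., 810 degrees) are exact vertex-wise midpoints of
  their neighbours, with a virtual apical profile beyond the sweep
  supplying the second neighbour of the 810-degree section;
* the auditory-nerve canal hugs the inner duct wall over roughly the
  scala-tympani height (the osseous spiral lamina side), 1.2 mm deep,
  vanishing where the apical duct approaches the modiolar axis;
* a 20-degree fluid "hook" (scala tympani and vestibuli only) continues
  below the round window before the 0-degree sweep start. Without it the
  basal end of the duct is a bone-backed cap and carries far too little
  exit current; anatomically the basal scala tympani is a fluid
  continuation toward the round window;
* the organ of Corti is merged into the basilar-membrane label and the
  spiral ligament into bone, because the conductivity table assigns neither
  a separate value.

`loft_cochlea()` interpolates every polygon vertex across the control
sections with a natural cubic spline over insertion angle, giving a
continuous compartment model that passes exactly through the control
polygons, and carries the anisotropic scale factors.

## Discretization

`voxelize()` labels cell centers on a tensor-product rectilinear grid:
uniform fine cells (default 0.3 mm, the CBCT voxel size) inside the cochlea
bounding box, geometrically coarsened (ratio 1.5) out to the grounded
boundary. This replaces a tetrahedral body-fitted mesh; it is reproducible
without a CAD kernel and its convergence is tested by refinement (the
scala-tympani labelled volume changes by about 1% from 0.3 to 0.15 mm
spacing).

Two membranes are thinner than any affordable cell. They are dilated to one
cell thickness — toward the scala media, where the organ of Corti sits, so
the scala-tympani and -vestibuli boundaries stay resolution-invariant — and
the solver restores the physics with a sheet-resistance-preserving
effective conductivity: a membrane cell of axial size `dz` containing a
membrane of true local thickness `t` conducts as the series combination
`dz / (t/sigma_membrane + (dz - t)/sigma_fluid)`, so the trans-membrane
resistance is independent of the grid.

The electrode array (22 contacts; CI24RE 17 mm 0.8→0.5 mm diameter, or
CI422 20 mm 0.6→0.3 mm) is voxelized as a tapered silicone tube along the
contact curve with platinum bands proud of the carrier surface. Band
regions are capped at 0.45 mm radius so adjacent contacts can never fuse
into a continuous metal rod (which would short the basal turn and flatten
the potential profile); each contact keeps at least its nearest cell.
Manufacturer gap tables are not public, so inter-contact arc gaps default
to `length / 21`, overridable.

## The field solve

The stationary potential solves `div(sigma grad V) = 0` with the tissue
conductivities (S/m): electrodes 1000, scala media 1.67, scala tympani and
vestibuli 1.43, basilar membrane 0.0625, Reissner membrane 0.00098, nerve
0.3, bone 0.02, silicone 0.099. Permittivity is ignored (quasi-static).
The single fitted parameter is the scala-tympani-to-bone ratio
`R = sigma_ST / sigma_bone`; setting `R` keeps `sigma_ST` fixed and moves
the bone value, exactly as in the ratio optimization below.

Discretization is a 7-point finite-volume stencil with harmonic-mean face
conductances, so layered tissues act as series resistors and the discrete
fluxes are exactly conservative. Monopolar stimulation injects the total
current (default 106.5 uA) over the active contact's cells with
volume-proportional weights; contact recordings use the same weights, which
makes the simulated transimpedance matrix reciprocal to machine precision
(the operator is symmetric). Grounding is either a 50 mm bony sphere
(Dirichlet 0 V on the outermost in-sphere shell) or a far-field
approximation (domain padded to three times the sphere radius, Dirichlet on
the box boundary); convex combinations of per-mode solutions are available
for weighted grounding. The SPD system is factorized once with sparse
Cholesky (CHOLMOD) and reused across the 22 stimulating contacts, which is
what makes the 22-solve voltage matrix and the 20-point ratio grid
affordable.

Numerical accuracy, measured against the closed-form solution for a central
source in a uniform grounded sphere: the spherical-mean radial profile
matches within 0.3% from three cells outward; individual directions are
within 5% from four cells and within about 6% at three cells on-axis (the
intrinsic directional anisotropy of the 7-point lattice Green function —
the oracle tests therefore compare the spherical mean, plus single
directions from four cells).

## Current-path analysis

`current_path_fractions()` integrates the outward normal current density
over the duct boundary, partitioned into three labelled exit regions:
faces into the nerve canal (modiolus), the duct boundary over the first 25
degrees of the sweep including the hook (basal end / round window), and
everything else (lateral walls). The angular extent of the basal region is
a fixture property; the source publication gives no formal definition. At
the default grid the template model run yields roughly 16 / 22 / 62%
(modiolus / basal / walls) with the grounded sphere and nearly the same
under far-field grounding — the near-field partition is insensitive to the
ground distance — against published values of 24 / 20 / 56% and
16 / 30 / 54% respectively.

## Telemetry and validation

A voltage matrix stores the potential (mV) at every recording contact for
every stimulating contact; the diagonal is excluded everywhere because
self-recordings are dominated by the electrode-tissue interface. Measured
matrices are emulated by entrywise multiplicative Gaussian noise (default
CV 5%, seeded); no measurement-noise statistics are published, so the CV is
a configurable assumption.

The validation statistic subtracts each stimulating contact's mean over the
N-1 recorded contacts from both matrices (removing any common offset),
accumulates squared differences over all off-diagonal pairs, normalizes by
N(N-1) and takes the square root. As printed, the source formula sums
stimulating contacts only to N-1 while normalizing by N(N-1); the package
sums over all N stimulating contacts so the statistic is a true RMS and
symmetric in the contacts — an interpretation, documented here.

`optimize_R()` evaluates the forward model over a ratio grid (default 20
linear values on [9.16, 71.5]; the endpoints are scala-tympani conductivity
1.43 over the two literature bone conductivities 0.156 and 0.02) and
returns the grid argmin, ties broken toward the larger ratio.
`fit_hm_sigma()` fits the single conductivity of the homogeneous
point-source model by 1-D minimization over [0.1, 5] S/m; on synthetic
cohorts the fit regularly lands on the lower bound, because the homogeneous
model mainly needs an amplitude gain to approach duct-channelled profiles.

## The auditory-nerve population

7000 fibers (default) are spread along the full sweep. Each has 10 nodes at
a constant 0.35 mm internode distance (a morphological order-of-magnitude
value, configurable; the internode distance deliberately does not scale
with the patient factors, while node anchor positions do). Node 10, the
most peripheral, sits just below the basilar membrane near the inner duct
wall; the path runs radially inward and bends down the modiolar axis, with
nodes 10..6 dendritic, 5 the soma, 4..1 axonal.

The activation function is the second spatial difference of the
extracellular potential along the fiber, sampled at 10 um and aggregated to
the node positions; it is exactly zero on affine potentials and exactly
`2a` on quadratics `a x^2`. Firing uses node-10 activation only:
`P = Phi((A - A_thr) / (A_thr RS))` with per-fiber thresholds from a
log-normal distribution (SD/mean 0.3) and relative spreads from a clipped
normal (mean 0.0635, SD 0.04, clipped to [0.03, 0.10]). Because the
log-normal is right-skewed, the population fires at rate 1/2 at the
*median* threshold and at about `Phi(sdlog/2) ~ 0.557` at the mean — the
tests pin both.

Thresholds need an absolute scale ("0 dB" in activation units). The package
calibrates it to half the maximum node-10 activation at a reference
stimulus, so the mean threshold sits 6 dB below the activation peak and the
excited population is a localized cohort around the stimulating contact; a
median-based calibration was rejected because it would excite half of all
fibers. The depolarizing (positive) part of the second difference is used
as the activation; an absolute-value alternative can be substituted.

Spread statistics sample |V| at the node-10 positions against
basilar-membrane arc length: the peak location is the argmax and the 3 dB
bandwidth the contiguous extent above `10^(-3/20)` of the peak (amplitude
convention; the source does not state amplitude vs power). Excitation-site
classes follow the figure semantics (peripheral = strongest
supra-threshold node among 10..6, central = 5..1); the source text and its
figure captions disagree on this mapping, and the caption reading is used.

## The synthetic cohort

`generate_patient()` draws A, B, H uniformly within the published cohort
ranges (A in [7.50, 9.85], B in [5.49, 7.47], H in [4.01, 5.27] mm — 12
patients cannot support a fitted multivariate law), builds exact
anatomy-frame markers plus preop/postop frames under random rigid motions
with 0.15 mm marker jitter (the CBCT half-voxel), places the array along
the lateral scala-tympani wall at spec spacing with 0.3 mm jitter on the
raw estimates, draws a ground-truth conductivity ratio from the grid values
covering the published per-patient optimum range (30.30 to 71.50 — ratios
below that range were never observed in the cohort), and simulates
telemetry at that ratio with 5% multiplicative noise. Everything is seeded;
the same seed is byte-reproducible. A fixture mode returns the literal
published dimension table instead of sampling.

What passing tests on this cohort do and do not show: the generator's truth
*is* the forward model, so recovery and ordering results demonstrate
internal consistency and the information content of the telemetry geometry
— not fidelity to real cochleae. Real telemetry contains interface
impedances, tissue growth, measurement artifacts and anatomical detail that
no synthetic patient here carries.

## Problem sizes and numerical settings

Defaults: fine spacing 0.3 mm, coarsening ratio 1.5, 50 mm ground sphere
(about 1.7-2.4 x 10^5 unknowns, under a minute per factorization), solver
residuals ~1e-12 (direct factorization). The test-suite uses deliberately
reduced sizes: 0.6 mm for generic solver properties, 0.8 mm for the
cohort-level recovery and model-ordering checks (the ratio-recovery
check is run at reduced resolution by design: at fine grids the
better-resolved fluid ducts flatten the profiles and the between-ratio
signal shrinks relative to the telemetry noise floor, degrading recovery —
at 0.8 mm the 20-seed hit rate is 1.0), and the default 0.3 mm where the
result is resolution-sensitive in the opposite direction (the
bandwidth-variability comparison across the ratio grid, which under-coarse
grids quantize on the second-turn plateau).

## Known limitations

* The cross-section template is a stylized fixture; absolute potential
  magnitudes (tens of mV at neighbouring contacts for 106.5 uA) should be
  read as model-internal, not clinical, values.
* On the synthetic cohort the amplitude-fitted homogeneous model and the
  unscaled template land at practically the same mean validation error
  (within ~2%, either sign depending on discretization), unlike the
  published factor-two separation on real telemetry; the robust reproduced
  ordering is template > patient-specific > ratio-optimized
  patient-specific. The corresponding strict inequality is asserted anyway
  and fails at the tested resolution; see the test suite.
* Peak excitation location is R-invariant as published, but the absolute
  3 dB bandwidths depend on the fixture's duct taper, and their across-R
  variability only exceeds the across-geometry variability at the default
  (0.3 mm) resolution.
* No electrode-tissue interface impedance, no tissue growth, no capacitive
  effects, no anisotropic conductivity, no head model.
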