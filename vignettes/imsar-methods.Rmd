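---
title: "Image-based SAR mapping: models, filters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based SAR mapping: models, filters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsar)
```

## The problem

Clinical MRI scanners monitor only volume-averaged specific absorption rate
(SAR); the local SAR distribution — where radiofrequency heating actually
concentrates — is normally available only from electromagnetic simulations
that are far too slow to run during an exam. `imsar` implements an
image-based alternative: every quantity is derived from maps a scanner can
acquire in minutes, namely a B1+ magnitude map, the phase of a
balanced-SSFP-like sequence, and a tissue segmentation.

The chain is:

1. **Conductivity** from the measured phase by phase-based Helmholtz
   electrical properties tomography (EPT),
2. **E-field** from the complex B1+ field via Ampère's law,
3. **SAR** pointwise, then smoothed, outlier-cleaned, and corrected per
   tissue,
4. **10-g SAR** by mass-constrained cube averaging, separately corrected.

## Models and assumptions

### Transceive phase and phase-based EPT

For quadrature transmit/receive at 3 T the measured phase of a sequence
without significant off-resonance contribution approximates *twice* the
transmit (B1+) phase — the transceive phase assumption. Under locally
homogeneous electrical properties the Helmholtz equation for the RF field
reduces, for the phase part, to

$$\sigma \;=\; \frac{\nabla^2 \varphi_{tr}}{2\,\mu_0\,\omega},$$

which `conductivity_from_phase()` evaluates voxelwise. The assumptions
(local homogeneity, negligible B0 contamination, quadrature symmetry) fail
at tissue boundaries; everything the package does about that failure is in
the filtering below. Negative reconstructed values are retained in the raw
map as diagnostics of assumption failure but excluded from per-tissue means,
which would otherwise be biased by clipping or contamination.

### Savitzky–Golay derivatives with anatomical adaptation

All derivatives are coefficients of a local weighted least-squares quadratic
fit over a 3D footprint (`sg_kernel()`): the Laplacian is
$2(a_{xx}+a_{yy}+a_{zz})$, gradients are the first-order coefficients. Two
details matter numerically:

* the fit runs in footprint-normalised coordinates (order-1 numbers), and
  the coefficients are rescaled to SI afterwards; fitting directly in metres
  makes the normal equations catastrophically ill-conditioned
  ($10^{-3}$-scale coordinates raised to fourth powers);
* a voxel whose footprint retains fewer usable neighbours than monomials
  (10 for degree 2), or a singular system, is returned as `NA`
  ("unreconstructable") rather than extrapolated.

Anatomical adaptation weights footprint voxel $j$ by
$\exp\!\big(-(R_j-R_0)^2 / (2 (w\,\Delta R)^2)\big)$, where $R$ is a
reference image (MPRAGE-like), $R_0$ its value at the centre voxel and
$\Delta R$ its foreground range. This suppresses differentiation across
tissue boundaries — the dominant EPT artefact. The Gaussian-in-intensity
form with scale $w\,\Delta R$ is this package's concrete reading of the
"weight parameter"; it is isolated in `sg_fit_weights()` so an alternative
semantics can be swapped in. Defaults follow the standard workflow: a
5×5×5 cuboid with $w=0.05$ for the phase Laplacian, an ellipsoid of
semi-axis 4 voxels for the B1+ derivatives, and an 11³ cube with $w=0.1$
for the conductivity postprocess (a weighted mean, i.e. the degree-0 case
of the same fit). "Size 5" and "size 10" are read as full footprint
extents realised symmetrically (5³, 11³); "size 4" for the ellipsoid as
the semi-axis. These conventions are inherited from an external filter
library that does not restate them; symmetric odd footprints keep the
estimate centred, which is what matters for unbiased derivatives.

### E-field closure and correction factors

MRI measures only the positively rotating component B1+. The package closes
the field as $B_x = B_1^+$, $B_y = -i B_1^+$, $B_z = 0$ and applies the
time-harmonic Ampère–Maxwell law
$\nabla \times (B/\mu_0) = (\sigma + i\omega\varepsilon)\,E$:

$$E_x = \frac{i\,\partial_z B_1^+}{\mu_0 y},\qquad
  E_y = \frac{\partial_z B_1^+}{\mu_0 y},\qquad
  E_z = \frac{-i\,\partial_x B_1^+ - \partial_y B_1^+}{\mu_0 y},
  \qquad y = \sigma + i\omega\varepsilon_0\varepsilon_r.$$

Neglecting B1− and Bz systematically *underestimates* |E| and hence SAR;
the tissue-specific correction factors (3.08/1.79/2.59 for pointwise SAR,
2.11/2.06/1.95 for 10-g SAR, gray matter / white matter / CSF) repair this
bias. They were derived externally from ensembles of anatomical models with
full-field reference simulations and are applied here as constants
(`correction_factor_table()`); deriving them is out of scope. The sign of
$i\omega\varepsilon$ follows the configurable time convention; |E| and SAR
are invariant to it, which the tests assert numerically.

Conductivity entering the E-field step is the piecewise-constant per-tissue
mean map — individual-voxel EPT noise would otherwise be amplified by the
division. Permittivity is never reconstructed: it is expanded over the
label map from literature values (at 128 MHz: εr 73.5 / 52.5 / 84.0 for
GM / WM / CSF, conductivities 0.59 / 0.34 / 2.14 S/m).

### SAR and 10-g SAR

Pointwise, $\mathrm{SAR} = \sigma\,(|E_x|^2+|E_y|^2+|E_z|^2) / (2\rho)$
with $\rho = 1000\ \mathrm{kg/m^3}$ and stored amplitudes treated as peak
values (the factor 2 yields the time average). The fixed processing order
is: pointwise SAR → Gaussian smoothing (σ = 0.4 *voxels*; the bare value is
dimensionless in the source workflow, and in millimetres it would be
sub-voxel and meaningless at 2.3 mm spacing) → one-pass outlier removal at
mean + 9 SD (removed voxels become undefined, never clamped, so they drop
out of every downstream statistic) → tissue correction. Smoothing is
mask-renormalised: background never bleeds into tissue.

The 10-g map grows, per tissue voxel, a centred axis-aligned cube by whole
half-widths, counting *only tissue mass*, and stops at the smallest cube
reaching 10 g; near air boundaries the cube grows larger rather than
including air. Whole-voxel growth can overshoot 10 g by up to one shell;
the returned mass map makes the overshoot auditable. Fractional-shell
(IEC-style) refinement and non-cubic averaging regions are deliberately out
of scope. Averaging runs on the *uncorrected* SAR; the 10-g factor table is
applied afterwards, keyed by the centre voxel's tissue — the pointwise and
10-g corrections are calibrated separately and do not compose.

## The synthetic phantoms

`phantom_spec()` / `generate_phantom_inputs()` produce fully synthetic,
forward-consistent input sets so the entire chain is testable without
scanner data:

* **sphere** — homogeneous distilled-water object (σ = 0.01 S/m, εr = 80);
* **vials6** — six cylindrical compartments at 0.16, 0.32, 0.39, 0.46,
  0.56, 0.75 S/m (dielectric-probe values for graded saline) in a
  water-filled container, on the 128×128×35 grid at (2.3, 2.3, 2.5) mm;
* **brainlike** — nested CSF/GM/WM ellipsoids with CSF ventricles.

The transceive phase is built from the inverse model's own identity: inside
each region $\varphi(r) = (\mu_0\omega\sigma/3)\,|r-c|^2$, whose Laplacian
is exactly $2\mu_0\omega\sigma$. This tests the implemented inverse
*exactly*, which is the point — the real ground truth would come from a
full-wave solver, and simulating one is out of scope. Consequences to keep
in mind when reading test results:

* phase continuity across region boundaries is *not* enforced; boundary
  voxels are excluded from recovery assertions, mirroring where Helmholtz
  EPT genuinely fails on real data;
* the quadratic bowl has none of the curvature-model error a real birdcage
  phase has, so recovery tests certify the filtering and algebra, not the
  physics approximation;
* the B1+ magnitude is a smooth centre-bright radial profile (peak 5 μT, a
  typical 3T transmit amplitude) — adequate for derivative/SAR plumbing,
  not a coil simulation.

Noise defaults are 0.01 rad phase SD and 1% relative magnitude noise at
seed 1234; the whole generator is a pure function of its spec. The
reference volume assigns flat per-region intensities chosen so that
*spatially adjacent* regions contrast strongly (vials 0.6–1.0 against water
0.15; WM 1.0 / GM 0.6 / CSF 0.2, a T1-like ordering) — the property an
anatomical reference must have for adaptive filtering to work, and the one
real MPRAGE/bSSFP contrast provides. With many regions in one image it is
not possible to separate *every pair* beyond the $w=0.1$ discrimination
scale, only the spatially adjacent ones; recovery statistics therefore use
region interiors (`region_interior_mask()`, two kernel half-widths).

## Numerical and design choices

* **Grids**: arrays are indexed (x, y, z), spacing in mm; all inputs are
  resampled (trilinear; nearest for labels) onto the phase grid, assumed
  already co-oriented — no affine registration. Out-of-support voxels are
  background 0 and excluded downstream.
* **Interpolation kernel**: the source workflow does not state its
  resampling kernel; trilinear is assumed for images.
* **Frequency**: 128 MHz by default, but logged and overridable — some 3T
  systems operate near 123 MHz and the EPT scale is proportional to ω.
* **Outlier SD = 0 degenerate case**: a uniform map removes nothing
  (threshold equals the mean, removal is strictly-above).
* **Peak ties** break to the lowest linear index, deterministically.
* **Undefined voxels** propagate as `NA` through every stage and are
  excluded symmetrically from all two-map metrics.
* **Quartiles** use linear interpolation (type 7) — fixed because IQR
  values are compared across maps; skewness is the adjusted
  Fisher–Pearson form.
* **Concentric comparison regions** (center/middle/outer) are equal-width
  thirds of normalised centroid distance over the foreground; the
  partition is configurable since no canonical definition exists.

## Problem sizes used in the shipped tests

Unit and property tests run on 9³–31³ toy volumes where brute-force
oracles (dense per-voxel weighted least squares, finite-difference curls,
exhaustive 10-g recounts) are exact and fast. End-to-end phantom tests use
the full 128×128×35 acquisition grid for the six-vial recovery and a
48×48×16 brain-like object for pipeline-level properties; the full-grid
brain-like run (the determinism check) takes a few seconds of compiled
filtering per stage.

## Known limitations

* The forward phantom validates the inverse exactly by construction; it
  cannot detect model error of the Helmholtz approximation itself on
  realistic fields.
* Correction factors are constants per tissue; subject-specific deviations
  from the ensemble they were derived on are not modelled.
* Skull/skin are outside the label set: like the source workflow, the
  package maps only GM/WM/CSF.
* The EPT weight semantics of the external filter library are not public;
  the Gaussian-in-intensity reading here is explicit, logged, and swappable
  (`sg_fit_weights()`).
* B1+ magnitude in arbitrary units propagates to arbitrary SAR units; the
  absolute scale is only meaningful when the input is in tesla (the
  phantom default).
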