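---
title: "Microwave scattering forward models for differential stroke detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave scattering forward models for differential stroke detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mwihead)
```

## The problem

Microwave tomography for brain stroke relies on a simple physical fact: a
haemorrhage (pooled blood) raises the relative permittivity and conductivity
of the affected tissue well above healthy brain values, while an ischaemic
clot lowers them. An array of antennas around the head transmits at around
1 GHz, one element at a time, and the scattered field encodes where the
dielectric anomaly sits. Before any hardware is built, these systems are
designed in simulation: a labelled head phantom is given frequency-dispersive
tissue properties, the time-harmonic wave equation is solved once for the
healthy head and once per stroke scenario, and the difference of the field
magnitude maps, `D = | |E_normal| - |E_stroke| |`, is inspected for a peak at
the anomaly. `mwihead` implements that whole forward chain as tested R code.

## Model and assumptions

The solver discretizes the scalar TMz reduction of the time-harmonic wave
equation under the `exp(+j omega t)` convention,

$$\nabla\cdot(\mu_r^{-1}\nabla E_z) + k_0^2\Big(\varepsilon_r -
  j\frac{\sigma}{\omega\varepsilon_0}\Big)E_z = j\omega\mu_0 J_z ,$$

with non-magnetic tissue (`mu_r = 1`), piecewise-constant per-cell dielectric
coefficients, first-order nodal triangles (each grid cell split in two, which
makes tangential-field continuity across tissue interfaces automatic), a
stretched-coordinate perfectly matched layer on all sides and a homogeneous
Dirichlet wall behind it. A coarse 3D scalar variant uses 7-point finite
differences on the voxel grid with the same PML, each equation scaled by the
product of the stretch factors so the operator stays complex symmetric.

Assumptions worth keeping in mind:

* **Scalar 2D core.** The production analyses run on a 2D slice through the
  stroke plane. Out-of-plane scattering and polarization coupling are absent,
  so absolute field values are not comparable to a full 3D vector solve; the
  differential quantities (peak location of `D`, contrast orderings, SAR
  margins of two orders of magnitude) are the claims the package makes.
* **Point-fed elements.** Each array element enters the 2D solve as a line
  current at its feed position, spread bilinearly onto the four surrounding
  nodes so the source location is independent of the mesh. The full dipole
  geometry is used only by the analytic impedance model.
* **Power calibration.** A 2D line current radiates
  `P = omega mu0 |I|^2 / 8` watts per metre in free space; amplitudes are
  calibrated so this per-metre power equals the configured transmit power
  (default 6.6 mW), which keeps SAR results comparable across runs.

## Tissue dielectrics

Each of the 21 canonical tissue classes carries a fourth-order relaxation
model

$$\tilde\varepsilon_r(\omega) = \varepsilon_\infty + \sum_{m=1}^{4}
  \frac{\Delta\varepsilon_m}{1 + (j\omega\tau_m)^{1-\alpha_m}} +
  \frac{\sigma_s}{j\omega\varepsilon_0},$$

evaluated on the principal branch (which guarantees passivity,
`sigma(omega) >= 0`). Seventeen classes use the Debye special case
(`alpha = 0`, trusted over 0.1--3 GHz); four use the broadened Cole-Cole
form. The shipped parameter file `head_dispersion_synthetic.csv` is a
synthetic stand-in: per tissue, a plausible relaxation skeleton (water-like
8.8 ps main pole plus three slower minor poles) is fixed and the main pole
amplitude and static conductivity are solved linearly so that the 1 GHz
evaluation reproduces the published per-tissue `(eps_r, sigma)` table to
better than 1e-9 (`data-raw/fit_dispersion_params.R` documents the fit). The
file reproduces the table's 1 GHz values exactly by construction; its
frequency dependence is representative, not source-accurate.

Stroke tissue is overridden with fixed 1 GHz constants: haemorrhagic
`(61.0650, 1.5829 S/m)`, ischaemic `(30, 0.5 S/m)`; a user-supplied
`override` in `stroke_spec()` replaces them, which is also the hook for a
dispersive stroke model.

## The synthetic head

`generate_layered_head()` builds seven strictly nested ellipsoidal shells
(skin, fat, cortical bone, CSF, dura, grey matter, white matter) in air, with
an outer shell of 90 x 110 x 120 mm semi-axes -- adult-head scale, consistent
with a 3--4 cm antenna standoff. Voxels take the label of the innermost
shell containing their centre, so every geometric claim is brute-force
verifiable; the construction is deterministic and mirror-symmetric.

What it emulates: the layer ordering and thicknesses that control wave
penetration, a grey-matter band around a white-matter core (so the frontal
stroke sits in GM and the lateral stroke in WM, giving the two contrast
regimes), and realistic per-layer dielectrics. What it does not emulate:
anatomical asymmetry, gyri/sulci, ventricles, or segmentation noise of a real
MRI-derived phantom. Passing tests on this phantom therefore demonstrate the
*method* (localization by differential field magnitude, contrast ordering by
host tissue) under clean geometry; performance on a real head will be
degraded by anatomical clutter, and the package makes no claim about that.
Zubal-style raw uint8 label grids can be read with `read_voxel_phantom()` and
mapped onto the 21 canonical classes with `map_tissues()` when such data are
available.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| frequency | 1e9 | Hz | penetration/resolution compromise for head imaging |
| cell size (2D scene) | 2 | mm | ~18 cells per wavelength in CSF, resolves the 10 mm stroke |
| array | 8 elements, 35 mm standoff | -- | elliptical ring, element 1 at +x, 7 facing the nose |
| transmit power | 6.6e-3 | W | feed calibration target |
| stroke radius | 10 | mm | sphere at (0,-70), (0,0), (22,0) mm in the z = 26.6 mm plane |
| solver tolerance | 1e-3 | relative residual | production solves |
| PML | 24 mm deep, order 3, target reflection 1e-6 | -- | held fixed in mm across mesh ladders |
| mesh ladder | 6, 4.5, 3.5, 2.8, 2.3, 2 | mm | all within lambda/5 in CSF; finest last |
| convergence tolerance | 1e-3 | V/m | absolute probe-|E| difference vs the finest model |
| SAR density | 1050 | kg/m^3 | uniform head average; limit 2 W/kg |

## Numerical choices

* **Krylov solvers.** GMRES (restart 60), FGMRES and BiCGStab are written in
  R over compiled complex sparse kernels; no installed R package offers
  complex sparse iterative solvers, so these are first-class, tested code.
  The independent cross-check is a direct sparse LU of the equivalent
  `2n x 2n` real system via `Matrix`.
* **Preconditioner.** ILU(0) (compiled) of a complex-shifted copy of the
  operator: the mass term is multiplied by `(1 - j beta)` with `beta = 0.5`
  before factoring -- the shifted-Laplacian device that keeps ILU-type
  preconditioning convergent on interior-lossless Helmholtz problems.
  `beta = 0` gives plain ILU(0).
* **Residual vs field error.** The stopping rule bounds the relative
  residual. On these discretizations the field error runs one to two orders
  above the residual (the operator's conditioning), so method-to-method
  agreement is asserted where it is sharp: the probe-point |E| values of
  GMRES/FGMRES/BiCGStab agree to well within ten times the tolerance, while
  whole-field L2 agreement is checked against a looser 5% sanity bound.
* **Convergence protocol.** The mesh ladder is solved with the direct solver
  so that the probe differences measure discretization error only, not
  iteration error. The probe-|E| difference against the finest model is not
  monotone in cell size -- re-voxelizing the ellipsoidal shells at each cell
  size moves tissue boundaries by up to half a cell -- and the protocol's
  job is exactly to pick the coarsest model inside the tolerance despite
  that; under the defaults it selects model 4 (2.8 mm) at ~9.5e-4 V/m.
* **Probe sampling and peak search.** Probe values are bilinear
  interpolations on the node grid (nodal values are not uniquely defined at
  arbitrary physical points); in the planar analysis the top/bottom probes of
  the seven-point set project onto the stroke centre. The peak search for
  the difference map excludes nodes within a 2-cell rind of the head surface,
  where source proximity dominates the differential signal.
* **Degenerate inputs.** Zero-amplitude sources yield an exactly zero field;
  identical normal/stroke fields report "no contrast" instead of a peak;
  non-convergent solves raise a typed error carrying the residual history,
  never a silent partial answer.

## Problem sizes

The shipped analyses are desk-scale by design: the 2 mm production scene has
about 3.2e4 complex unknowns (169 x 189 cells), the free-space validation
runs at lambda/48 sampling (~6e4 unknowns), the mesh ladder spans 3.6e3 to
3.2e4 unknowns, and 3D checks use small grids (2.5e4--5e4 unknowns) where the
scalar finite-difference operator is exercised end to end. A full stroke
experiment (10 solves) takes a few minutes on one core.

## Known limitations

* Scalar physics: no polarization effects, no vector edge elements; absolute
  E-field and SAR values are 2D analogs, not dosimetry-grade 3D numbers.
* The synthetic dispersion file is exact only at 1 GHz; off that frequency it
  is a representative relaxation model, not a measured table.
* The skin-layer SAR peak is a resolution-dependent statement: at very coarse
  cells (>= 4 mm) the one-cell-thick skin shell mixes with its neighbours and
  the peak can land in the adjacent high-conductivity CSF; at the 2 mm
  production spacing it sits in skin for every surveyed element.
* No coupling medium between array and head is modelled; elements radiate in
  free space.
* Image reconstruction (the inverse problem) is out of scope; the package
  produces the forward data an inversion would consume.
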