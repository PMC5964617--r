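---
title: "Methods: coupled EM-thermal modelling of slot-antenna microwave ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled EM-thermal modelling of slot-antenna microwave ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwablate)
```

## The model

`mwablate` simulates interstitial microwave ablation of breast tissue with a
2.45 GHz double short-distance slot coaxial antenna: a UT-085 semi-rigid coax
(inner conductor radius 0.255 mm, dielectric 0.84 mm, outer conductor
1.10 mm) inside a 1.29 mm PTFE catheter, with two annular slots cut in the
outer conductor 0.40 mm apart (centre to centre) and a closed metal tip
beyond the distal slot. The antenna is assumed to lie along the axis of a
cylindrical tissue block, which reduces the problem to the axisymmetric
(r, z) half-plane.

The computation is a one-way coupled chain:

1. **Electromagnetics.** Time-harmonic Maxwell equations at the operating
   frequency, in the azimuthal-magnetic-field formulation. With
   $H = H_\phi(r,z)\,\hat\phi$ and complex effective permittivity
   $\varepsilon_c = \varepsilon_r - j\sigma/(\omega\varepsilon_0)$ per
   region, the field satisfies
   $\nabla \times (\varepsilon_c^{-1} \nabla \times H) - k_0^2 H = 0$.
   The solver works in the scaled unknown $v = r H_\phi$, whose weak form
   carries a $1/r$ weight. This choice is structural, not cosmetic: the
   coaxial TEM mode is $H_\phi \propto 1/r$, i.e. $v = \text{const}$, which
   linear elements represent exactly. In the unscaled variable the discrete
   line is effectively below cutoff and the port wave decays instead of
   propagating — a failure mode caught by the matched-coax verification test.
2. **SAR.** The volumetric heat source is
   $Q_{ext} = \tfrac12 \sigma |E|^2$ per element, with
   $E = (\nabla\times H)/(j\omega\varepsilon_0\varepsilon_c)$ evaluated at
   element centroids. Lossless regions (coax dielectric, slots, catheter)
   deposit nothing.
3. **Bioheat.** The Pennes equation
   $\rho C\,\partial T/\partial t - \nabla\cdot(k\nabla T) =
   \rho_b C_b \omega_b (T_b - T) + Q_{met} + Q_{ext}$,
   solved on the same mesh. The stationary form is available as printed; the
   transient extension (backward Euler) exists because the reported results —
   per-second sensor traces and maxima over a finite heating interval — are
   time-resolved quantities. Perfusion enters as a positive reaction term
   with the volumetric coefficient
   $\omega_b[{\rm 1/s}] = \omega_b[{\rm mL/min/kg}]\cdot 10^{-6}/60\cdot\rho$.

## Boundary conditions and the port

* **Metal** (inner/outer conductor, tip) is excluded from the mesh; its
  surface is a natural boundary of the $H_\phi$ formulation, which is exactly
  the perfect-electric-conductor condition. This is the standard treatment of
  metal at 2.45 GHz.
* **Port.** The coax cross-section at the tissue surface carries a
  first-order matched condition with a unit-amplitude incident TEM mode,
  scaled so the *forward* wave carries exactly the configured input power —
  the quantity a generator reports. Because both incident and reflected TEM
  fields share the $1/r$ profile, S11 is extracted by overlap of the
  scattered field $v - v_{inc}$ with the mode. Higher coax modes are
  evanescent on the sub-millimetre annulus and are ignored.
* **Outer boundary.** A first-order absorbing (scattering) condition matched
  to the local medium's $\sqrt{\varepsilon_c}$, rather than a PML: tissue
  loss attenuates the field before the boundary, and the power-balance
  invariant (deposited + radiated = delivered, enforced at 2%) guards the
  choice on every solve.
* **Axis.** $v = r H_\phi = 0$ is essential at $r = 0$; all quadrature points
  are strictly interior to elements so $1/r$ integrands are never evaluated
  on the axis.
* **Thermal.** The outer tissue boundary is held at the initial temperature
  (far-field); metal interfaces and the port plane are adiabatic; the
  catheter conducts with no contact resistance.

## Meshing

No triangular mesh generator exists in this R stack, so the package uses a
deterministic graded tensor-product triangulation: the breakpoint sets in r
and z contain every material interface line (conductor radii, slot edges,
tip, catheter cap), cells are classified by their centres, metal cells are
removed (their exposed edges become tagged `metal_surface` boundaries), and
each cell is split into two triangles with an alternating diagonal. Element
size is the configured minimum (default 0.15 mm) at the antenna and slot
band and grows geometrically (factor 1.3, capped at 3 mm; 1 mm along the
feed) toward the far boundaries. The default scenario meshes to roughly
3,700 triangles — the same order as the mesh the published model reports.
Feature-imposed intervals (e.g. the 0.10 mm metal ring between the slots)
bound the smallest edges; the mesher never subdivides below half the target
size.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Breast: $\varepsilon_r$, $\sigma$, $k$, $\rho$, $Q_{met}$ | 5.14, 0.14 S/m, 0.42 W/mK, 1020 kg/m³, 3.9 W/m³ | published model constants, used as printed |
| Breast specific heat | 3000 J/(kg K) | not published for this model; representative literature value for breast/fat, overridable per scenario |
| Blood $\rho_b$, $C_b$, $\omega_b$, $T_b$ | 1000, 3639, 33 mL/min/kg, 37 °C | published constants |
| Phantom | $\varepsilon_r$ 5.38, $\sigma$ 0.16 S/m; breast thermal constants; no perfusion/metabolism | measured dielectric values; the phantom has no physiology |
| Coax dielectric / catheter | $\varepsilon_r$ 2.03 / 2.60, PTFE thermal constants (0.25 W/mK, 2200 kg/m³, 1050 J/kgK) | dielectric values published; thermal values standard PTFE |
| Slot width | 0.30 mm | never printed; chosen from the drawing's proportions and typical slot construction — the single most result-sensitive unstated parameter |
| Slot spacing | 0.40 mm centre-to-centre | printed value. Note the stated design rule $0.025\,\lambda_{eff}$ evaluates to ≈1.35 mm with $\varepsilon_r = 5.15$; the formula and the printed 0.40 mm are mutually inconsistent. The geometry uses 0.40 mm as printed and `effective_wavelength()` exposes the formula as-is; the two are deliberately not reconciled. |
| Tip length | 0.50 mm beyond the distal slot | shown but not dimensioned |
| Tissue block | radius 30 mm, height 80 mm | far enough that the 60 °C isotherm never reaches the boundary (asserted at run time) |
| Sensors | slot midpoint and 1.0 cm proximal, both at the catheter surface (r = 1.29 mm) | sensor radius is not dimensioned ("next to the antenna"); the catheter surface is the closest physically realisable position |
| Initial temperature | 37 °C in vivo, 25 °C phantom | body temperature; room-temperature solidified phantom |
| Time step | 0.5 s | half the 1 s sensor sampling; backward Euler is unconditionally stable, and halving dt moves the reported maxima by ≈0.3% |

"Maximum temperature" is the maximum of the sensor trace over the heating
interval (traces are monotone during heating, so this equals the final-time
value; the definition survives non-monotone cases). No cool-down phase is
simulated. The 60 °C lesion area is a plane area of the 2D temperature map
on the full mirrored cross section (twice the half-plane measurement), with
the isotherm located by linear interpolation inside each element; published
lesion maps are drawn on that mirrored section, but whether the printed
areas are half-plane or full-plane measurements is genuinely ambiguous — the
2× convention is a documented assumption.

## Verification fixtures

The `synthetic_fixtures` layer makes the whole pipeline testable without any
measurement data:

* `manufactured_solution_pair()` prescribes smooth trigonometric fields that
  are regular on the axis and computes the exact source terms for both
  operators; every case is re-validated by Richardson-extrapolated numeric
  differentiation (residual < 1e-8) before it is allowed near a solver.
  Under uniform refinement both solvers show the expected second-order L2
  convergence (the test bar is order ≥ 1.8).
* `perfused_slab_analytic()` is the closed-form cosh profile of the 1D
  perfused slab, cross-checked in the tests against an independent
  finite-difference solve at 10⁴ points.
* `synthetic_sensor_trace()` emulates a fibre-optic recording as a
  saturating exponential toward a perfusion-limited plateau plus seeded
  Gaussian noise. It exists to exercise the model-versus-measurement
  comparison bookkeeping, not to imitate physiology: it has no inter-animal
  variability, no probe drift, and a single time constant.

Passing these tests shows the solvers converge to the equations' solutions
under the stated conditions. It does not show that the model reproduces
living tissue: dielectric and thermal properties are temperature-independent
here (deferred by the source model as well), there is no vaporisation or
phase change above 100 °C, and no tissue-damage kinetics.

## Numerical choices

* Quadrature: 3-point degree-2 rule with interior points (barycentric
  (2/3, 1/6, 1/6) permutations) for all volume terms, 2-point Gauss on
  boundary edges — documented so element-matrix oracles are reproducible.
* The complex system is solved as the equivalent real 2N×2N block system by
  sparse LU (the sparse complex factorization is not available here); the
  thermal systems use sparse Cholesky, factored once per time-step size and
  reused across all backward-Euler steps.
* `point_locate()` resolves ties (points on shared edges/vertices) toward
  the triangle with the largest minimum barycentric weight, then the lowest
  index; weights are clipped to [0, 1] and renormalised.
* Degenerate inputs fail loudly with classed conditions: zero-width slots,
  non-increasing radii, insertions that leave the tip too close to the
  boundary, pure-Neumann zero-perfusion steady solves, non-finite transient
  states, |Γ| ≥ 1.

## Problem sizes used by the tests and the acceptance script

The four protocol runs use the default 0.15 mm minimum element size
(≈3,700–4,200 triangles) and 0.5 s steps (≤240 implicit steps); each runs in
seconds. Convergence studies use uniform rectangle meshes at 8–64 cells per
side. These sizes are the package's defaults for desk-scale runs; all of
them are configurable.

## Known limitations

* The SAR within ~0.5 mm of the slot apertures is dominated by the
  edge-singular near field, so the slot-midpoint sensor (0.19 mm from the
  aperture) is sensitive to the unprinted slot width and to mesh resolution
  at the few-percent level; successive mesh halvings move it by ~2–3 °C.
* With the published breast-fat dielectric constants the modelled applicator
  is strongly mismatched (the computed SWR is far above the bench-measured
  1.077, which was obtained in a lossy tumour phantom). Input power is
  defined as *forward* power; only the transmitted fraction heats tissue.
  Consequently the simulated heating is more slot-concentrated than the
  published model's own temperature tables, whose geometry details (slot
  width, tip, sensor radius, boundary conditions) are not printed.
* Temperatures above 100 °C are reported as computed; the model contains no
  vaporisation physics, a known artefact it shares with the published model.
* First-order absorbing boundaries reflect weakly at grazing incidence; the
  power-balance check (2%) bounds the consequence.
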