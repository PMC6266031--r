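---
title: "Methods: the pencil-beam engine, its beam database and its evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pencil-beam engine, its beam database and its evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pencilbeam)
```

## The model

`pencilbeam` performs forward dose calculation for actively scanned proton
and carbon-ion beams. A plan is a set of spots, each defined by an energy, a
transverse position at the isocenter plane and a particle number. The dose at
a voxel is the superposition

$$ D(\mathbf{x}) \;=\; \sum_{\text{spots}} N \; \mathrm{IDD}\!\left(z_\mathrm{wed}\right)\;
   L\!\left(r;\, \sigma_i(z_\mathrm{wed}),\, w_i(z_\mathrm{wed})\right), $$

where $z_\mathrm{wed}$ is the water-equivalent depth of the voxel along the
spot axis, $\mathrm{IDD}$ the integrated depth dose per primary
(Gy·mm²), $r$ the perpendicular distance to the axis, and $L$ the
triple-Gaussian lateral kernel

$$ L(r) = \sum_{i=1}^{3} \frac{w_i}{2\pi\sigma_i^2}
   \exp\!\left(-\frac{r^2}{2\sigma_i^2}\right),\qquad \sum_i w_i = 1 , $$

which integrates to one over the transverse plane, so the product has units
of dose. The three components model the primary core, the halo of
large-angle scattering and the nuclear-secondary tail. The tabulated
$\sigma_i(z)$ contain the in-water spreading; the in-air spot width
(from the FWHM-in-air table) and the range-shifter widening are added in
quadrature onto *each* component. Whether a facility composes the
range-shifter term per component or onto an effective single width is not
standardized; per-component composition is this package's documented choice,
and it is exact in the single-component limit.

Alongside dose, the engine accumulates the dose-weighted sums
$\sum d\cdot \mathrm{LET}_d$, $\sum d\cdot\alpha$, $\sum d\cdot\sqrt\beta$
and $\sum d\cdot z^{*}_\mathrm{mix}$, from which the dose-averaged LET map
and the mixed-field radiobiological coefficients are formed by dividing by
dose. The biology tables depend on depth only; lateral variation of the
mixed field is deliberately not modelled (a known approximation of
engine-style calculations; the error concentrates at lateral field edges of
carbon beams).

## The synthetic beam database

Facility beam databases are produced by Monte-Carlo transport; this package
generates an analytic stand-in so that the whole chain is reproducible and
testable. The generator's formulas and constants are part of the package
contract:

* **Range-energy**: $R = aE^{p}$ mm with $a = 0.022$, $p = 1.77$ for
  protons (MeV), and $a = 0.022/3$ for carbon (MeV/u), the $1/3$ reflecting
  the $A/Z^2$ scaling of stopping power. A 150 MeV proton thus ranges
  ≈156 mm; generated Bragg-peak positions match the power law within 2%.
* **Depth dose**: the power-law stopping $dE/dz = (R-z)^{1/p-1}/(p\,a^{1/p})$
  is convolved numerically with a Gaussian range-straggling kernel
  ($\sigma_R = 0.012\,R^{0.935}$ for protons, about a third of that for
  carbon) on a 0.25 mm grid, then sampled onto the database grid
  (0.5 mm by default) and converted to Gy·mm² per primary. Carbon curves add
  a parametric fragmentation tail (12% of the peak, 20 mm decay length,
  switched on smoothly at the range), so the distal dose sits between 5%
  and 30% of the peak just past it.
* **Lateral widths**: a Highland-flavoured multiple-scattering growth
  $\sigma_\mathrm{MCS}(z) = \sigma_\mathrm{end}(z/R)^{1.8}$ with
  $\sigma_\mathrm{end} = 0.0205R$ (protons) or $0.0065R$ (carbon) defines the
  core; $\sigma_2$ and $\sigma_3$ are affine in $\sigma_1$, and the core
  weight decreases with depth as the halo builds up.
* **LET and biology**: LET$_d$ rises into the peak as a power of residual
  range and decays in the tail, with the proton table representing only the
  proton/deuteron/triton component by construction. Carbon $\alpha(z)$ and
  $z^*_\mathrm{mix}(z)$ rise toward the peak with a distal maximum at the
  range (entrance-to-peak ratio at least 2), $\beta(z)$ varies weakly. The
  proton LQ tables are benign constants; the proton biological path never
  reads them.
* **Ancillary tables**: FWHM-in-air versus energy (decreasing, with a small
  seeded measurement-like scatter of ±2% emulating a measured table),
  the range-shifter angular spread from the Highland formula for the
  clinical 30 mm reference degrader (rescaled by $\sqrt{\mathrm{WET}/30}$
  for other thicknesses), and a piecewise-linear HU→RSP calibration with
  nodes at air/lung/adipose/water/soft-tissue/bone (HU 0 ↦ RSP 1 exactly).

The generator's `seed` only perturbs the measurement-like scatter, never the
physics shapes, so all structural invariants hold for every seed. What the
synthetic database does **not** emulate: nuclear buildup near the entrance,
energy-dependent halo anatomy, the exact MKM saturation correction (upstream
of the database by construction), and any facility-specific beam optics.
Passing tests therefore demonstrate the correctness of the *calculation
machinery* — raytracing, kernel superposition, mixed-field averaging,
metrics — not agreement with any particular facility's beam model.

## Geometry, raytracing and the two-grid scheme

Coordinates are right-handed in mm; the grid origin is the corner of voxel
(1,1,1), voxel extents are half-open $[\mathrm{lower},\mathrm{upper})$, and
voxel centers sit at $\mathrm{origin} + (i-\tfrac12)\,\mathrm{spacing}$ — an
explicit convention that removes half-voxel ambiguity. Radiological depth is
computed by exact Siddon-style traversal at the CT grid's own resolution
(midpoint voxel identification makes boundary rays unambiguous); dose is
scored at the voxel centers of a coarser dose grid (2 mm by default, 3 mm
for pelvic-scale problems), mirroring clinical two-grid practice. The
perpendicular distance to the spot axis is geometric, not water-equivalent.
The kernel is truncated at $3.5\,\sigma_3$ of the composed largest
component — the same bound as the splitting grid — which discards ≈0.2% of
the third component's mass at most; the energy-conservation test budgets 1%
for cutoff plus grid discretization together and observes ≈0.02%.

## Sub-pencil-beam splitting

In heterogeneous geometry a single axis cannot represent the fluence's
spread, so a spot is split into $n$ sub-beams on a square grid covering
$[-3.5\sigma, 3.5\sigma]^2$ of the in-air Gaussian (side
$\lceil\sqrt n\,\rceil$, kept odd; defaults 349 and 97 for head- and
pelvic-scale heterogeneity). All sub-beams share one width — the grid
spacing $s$ — and their weights are cell integrals of the *deconvolved*
Gaussian with $\sigma'^2 = \sigma^2 - s^2 - h^2/12$ (the $h^2/12$ term
removes the variance added by cell integration), renormalized to exactly 1
after truncation. By the Gaussian convolution identity the superposition
then reproduces the parent fluence; in homogeneous water the split and
unsplit calculations agree to ≤0.03% of the peak at both default counts,
which is the formal justification for skipping splitting in water phantoms.
Each sub-beam is raytraced on its own axis and carries $s$ (in place of the
full in-air width) in quadrature with the tabulated in-water sigmas.

## Biological dose

* **Protons**: $D_\mathrm{RBE} = 1.1\,D$, voxel-wise and exactly; the
  accumulators are untouched. Variable-RBE models are an extension point,
  not a default.
* **Carbon, LEM**: dose-averaged $\alpha$ and dose-averaged $\sqrt\beta$
  (the Zaider–Rossi mixed-field rule): $\alpha_\mathrm{mix} = \sum
  d\alpha/D$, $\beta_\mathrm{mix} = (\sum d\sqrt\beta / D)^2$.
* **Carbon, MKM**: $z^*_\mathrm{mix}$ is dose-averaged;
  $\alpha_\mathrm{mix} = \alpha_0 + \beta_0 z^*_\mathrm{mix}$ with constant
  $\beta_\mathrm{mix} = \beta_0$.
* **Photon-equivalent dose**: the LQ iso-effect inversion
  $D_\mathrm{RBE} = (\sqrt{\alpha_x^2 + 4\beta_x E} - \alpha_x)/(2\beta_x)$
  with $E = \alpha_\mathrm{mix} D + \beta_\mathrm{mix} D^2$, and the linear
  branch $E/\alpha_x$ when $\beta_x = 0$.

The mixed-field combination rules are the standard ones; the averaged
quantities themselves are named by the database contract. The photon
reference ($\alpha_x = 0.1$ Gy⁻¹, $\beta_x = 0.05$ Gy⁻²) and MKM parameters
($\alpha_0 = 0.13$, $\beta_0 = 0.05$) are configuration defaults chosen in
the range of clinical literature, not commissioning values; every shipped
test property is invariant to them. The LEM↔MKM comparison utility reports
the ratio map scaled by a caller-supplied clinical scaling value and derives
the scaling factor $D_{\mathrm{RBE,LEM},50}/D_{\mathrm{RBE,MKM},50}$ over
the region of interest.

## SOBP spot-weight optimization

The optimizer exists to produce homogeneous spread-out-Bragg-peak test plans
equivalent in role to TPS-optimized inputs; it is deliberately a damped
dose-ratio fixed point, not a constrained TPS optimizer. Energy layers are
database energies whose peaks tile the target's water-equivalent depth
extent (one extra layer proximal and distal); each layer carries a square
spot lattice (3 mm default) covering the lateral projection plus one sigma.
Because dose and all four accumulators are linear in the weights, each sweep
re-evaluates $D_\mathrm{RBE}$ from cached per-spot influence columns; every
spot's weight is rescaled by $(\mathrm{presc}/D_\mathrm{RBE}(\text{control
voxel}))^{\gamma}$ with $\gamma = 0.7$ — the control voxel is the spot's
Bragg-peak position clamped into the target's bounding box, so margin spots
and the extension layers are steered by the coverage they provide at the
target edge — after which the weights are renormalized so the target median
equals the prescription exactly. $\gamma$ is halved whenever the
homogeneity objective $\max|D_\mathrm{RBE}-\mathrm{presc}|$ over the target
would increase — making the objective non-increasing over accepted sweeps.
Iteration stops once the objective stagnates (improvement below $10^{-3}$ of
the prescription) *and* the target median is within tolerance (0.3%
default); non-convergence raises an error carrying the trace. The procedure
is deterministic: the same inputs give a bit-identical plan.

## Evaluation suite conventions

* **DVH / $D_x$**: histograms are evaluated exactly on the sorted voxel
  values; binning exists only for export. $D_x$ interpolates linearly
  between order statistics at the midpoint plotting positions
  $(n-i+\tfrac12)/n$ (planning systems differ here; this package's
  convention is fixed and pinned by tests — 100 voxels dosed 1..100 give
  $D_{50} = 50.5$, $D_2 = 98.5$).
* **Gamma index**: global normalization to the reference maximum, 2%/2 mm
  with a 10% low-dose threshold by default. The minimization searches a
  sphere of radius $3\times$DTA at step DTA/10 with trilinear
  interpolation, visiting offsets in order of increasing distance so the
  spatial term alone bounds the remaining search. An exhaustive fine-step
  oracle in the test suite bounds the interpolation error. The global
  normalization makes the index asymmetric under swapping reference and
  evaluated distributions; voxels with $\gamma = 0$ remain so.
* **QA statistic**: chamber doses are read from the computed map by
  trilinear interpolation; differences are (measured − calculated)
  normalized by the computed field maximum; the verdict requires
  $|\mathrm{mean}| \le 5\%$ and $\mathrm{sd} < 5\%$ over the chamber set
  (12 in the clinical protocol). The standard deviation uses the sample
  ($n-1$) denominator — the protocol text does not specify, so the choice
  is documented here and pinned by an exact arithmetic test.

## Numerical choices and degenerate inputs

Depth tables are linearly interpolated; beyond the table end the depth dose
and LET are zero while lateral/biological columns clamp. Off-grid energies
are blended between bracketing entries after aligning depth axes on the
Bragg-peak position, which avoids the double-peak artifact of naive
blending. Summation order is fixed (beam → spot → sub-beam → voxel-linear),
so results are bit-reproducible and independent of plan partitioning. The
triple-Gaussian fitter uses Levenberg–Marquardt on an unconstrained
reparameterisation (ordered sigmas via positive increments, simplex weights
via stick breaking, free amplitude) from four documented starts with sigma
ratios 1:2:4 around the profile's RMS radius; residuals are weighted by
radius (floored at one grid step), reflecting the annular area each sample
represents — a choice, since no canonical weighting exists. All-zero
profiles, empty regions of interest, rays that miss the grid, zero
directions and out-of-range energies fail loudly rather than silently.

## Problem sizes

The shipped tests and the acceptance script run, as the package's reference
study case, a 3 cm cubic target with proximal face at 12 cm in a
160×160×200 mm water tank at 2 mm CT and dose resolution (≈2250 spots, ten
energy layers), plus single-spot oracles on grids up to 40³ and gamma/DVH
fixtures of 8–20 voxels per side. These sizes were chosen so that every
oracle can be recomputed exactly alongside the engine while keeping the
whole suite runnable on a laptop core in minutes.

## Known limitations

No Monte-Carlo transport, no nuclear-halo depth correction beyond what the
database encodes, no lateral mixed-field correction, no spot-shape
asymmetry or beam divergence between magnets and isocenter, no deformable or
4-D geometry, no DICOM import, and the LEM/MKM inputs come from the database
rather than from track-structure first principles. The synthetic database is
qualitatively, not quantitatively, faithful to any facility.
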