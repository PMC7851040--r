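---
title: "Modelling convection-enhanced delivery on diffusion-MRI microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling convection-enhanced delivery on diffusion-MRI microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Convection-enhanced delivery (CED) infuses a therapeutic agent directly
into brain parenchyma through a catheter under positive pressure,
bypassing the blood-brain barrier.  Where the infusate actually goes is
governed by the tissue's anisotropic hydraulic permeability: in white
matter, fluid moves far more easily along axon bundles than across
them.  Planning models therefore need, per voxel, a permeability tensor
$K$ and a diffusivity tensor $D$.

`cedflow` builds both tensor fields from two complementary
diffusion-MRI products.  The diffusion tensor (DTI) supplies the local
fibre frame $E = [\vec e_1, \vec e_2, \vec e_3]$ and the fractional
anisotropy (FA) used to separate grey from white matter.  NODDI
compartment maps supply the extracellular-space volume fraction
$\mathrm{VF}_{ECS}$, which controls *how much* easier flow along the
fibres is.  The package's central modelling element is a pair of
closed-form laws $k_\parallel(\mathrm{VF}_{ECS})$ and
$k_\perp(\mathrm{VF}_{ECS})$ calibrated against creeping-flow
simulations through idealised axon lattices, replacing the constant
white-matter permeability eigenvalues of conventional DTI-only models.

## Governing equations

The tissue is treated as a rigid porous medium.  The interstitial flow
satisfies incompressibility and Darcy's law,

$$\nabla \cdot v = 0, \qquad v = -\frac{K}{\mu}\,\nabla p,$$

with a volumetric catheter source and $p = 0$ on the outer brain
surface.  Tracer transport follows an advection-diffusion-loss
equation,

$$\frac{\partial c}{\partial t}
  = -\nabla\cdot(v\,c) + \nabla\cdot(D\,\nabla c) - \lambda c,$$

with solute inflow $Q c_0$ at the catheter voxels and *zero solute
flux* through the outer boundary: the glia limitans lets fluid seep out
but blocks the tracer.  The loss term is first-order decay; the printed
rate (0.01 min$^{-1}$) is converted to SI once, in one audited
conversion module, like every other constant.

The equations are solved in the superficial-velocity formulation
exactly as written: porosity does not appear explicitly, matching the
rigid-tissue model the tensor calibration assumes.

## Tissue model

Voxels are classified from FA and the free-water fraction:
CSF where $\mathrm{VF}_{Water} > 0.99$ (tested first, since free water
can coexist with low FA), else white matter where $0.23 < FA < 1$,
else grey matter.  FA exactly 0.23 goes to grey matter (the lower
interval is closed at its top by convention).

* Grey matter: $D_{GM} = D_0 I$ with $D_0 = 1.54\times10^{-10}$
  m$^2$/s, and $K_{GM} = K_0 I$ with $K_0 = 4.22\times10^{-18}$ m$^2$.
* White matter: the measured water tensor is eigendecomposed,
  $D E = E\Lambda$, and rescaled to the tracer,
  $D_{WM} = (D_0/\bar\lambda)\, E \Lambda E^T$, so that
  $\mathrm{tr}\,D_{WM} = 3 D_0$ identically while anisotropy and
  orientation are preserved.  The permeability is transversely
  isotropic about $\vec e_1$:
  $K_{WM} = E\,\mathrm{diag}(k_\parallel, k_\perp, k_\perp)\,E^T$.
* CSF transport constants are not part of the calibrated model; they
  are exposed as configuration (`csf_properties()`, defaults $D_0$ and
  $10^{-13}$ m$^2$) and the simulator warns when the infusion volume
  touches CSF.  Validation phantoms confine the infusion to white
  matter.

Eigenvalues are floored at $10^{-12}$ (SI) so that noisy voxels still
yield positive-definite tensors; eigenvector signs are fixed (first
nonzero component positive) for reproducible reassembly.

In the *baseline* ("dti") mode the white-matter eigenvalues are the
literature constants $k_\parallel = 6.75\times10^{-15}$ m$^2$ and
$k_\perp = 4.22\times10^{-16}$ m$^2$ everywhere.  In the
microstructure ("noddi") mode they come from the laws below, evaluated
at each voxel's $\mathrm{VF}_{ECS}$.

## The permeability laws and their microscale origin

White matter is idealised as parallel rigid cylinders (radius
$r = 0.34\,\mu$m) on a triangular lattice; the extracellular fraction
fixes the spacing, $a = r\sqrt{2\pi/(\sqrt3(1-\mathrm{VF}_{ECS}))}$.
With the solid fraction $\varphi = 1 - \mathrm{VF}_{ECS}$, the
calibrated laws are the Tamayol–Bahrami form

$$k_\parallel = \frac{r^2}{2.97\,\varphi}\Big({-1.47} - 0.94\ln\varphi
  + 2\varphi - 0.5\varphi^2 - 0.039\varphi^4\Big)$$

and the Kuwabara form

$$k_\perp = \frac{r^2}{7.77\,\varphi}\Big({-1.56} - 1.04\ln\varphi
  + 2.05\varphi - 0.5\varphi^2\Big).$$

Both grow steeply with $\mathrm{VF}_{ECS}$; inputs outside the
calibration range $[0.15, 0.80]$ are clamped to its edges and counted.

One property of the published perpendicular coefficients deserves
emphasis: the bracket changes sign near
$\mathrm{VF}_{ECS} \approx 0.295$, so the printed $k_\perp$ form is
*negative* over roughly half of its own calibration range.  `cedflow`
implements the printed form faithfully and documents the sign change;
positivity assertions in the test suite are restricted to the
subrange where the closed form is positive, and the sign change also
dictates the fitting objective below.

`microscale_sweep()` reproduces the calibration pipeline from scratch:

* **Axial flow.** Fully developed Stokes flow along the fibres reduces
  exactly to a 2-D Poisson problem for the axial velocity on the fluid
  cross-section, $-\mu\nabla^2 w = \Delta p/L$, with no-slip on the
  fibre walls.  The circular walls enter through a Shortley–Weller
  stencil (exact wall distances along grid lines), which makes the
  solver second-order accurate; halving the default 128-cell resolution
  changes the permeability by well under 1%.
* **Transverse flow.** 2-D Stokes flow across the lattice is solved on
  one periodic cell with a staggered (MAC) discretization, velocity
  unknowns on faces and pressures in cells, driven by a uniform body
  force equal to the mean pressure gradient $\Delta p/L$.  The
  periodic-cell formulation is the homogenisation-standard equivalent
  of an inlet/outlet pressure difference with *zero* entrance effects,
  and was preferred over a multi-cell strip for exactly that reason.
  The lattice's mirror symmetry about the fibre rows halves the
  domain.  In the dilute limit the computed permeability agrees with
  Kuwabara's classical cell-model closed form to within a few percent.
* **Darcy back-out.** $k = \bar v \mu L/\Delta p$ with $\bar v$ the
  superficial (full-cell) mean velocity; the result is independent of
  $\Delta p$ and $\mu$ in the creeping regime, which the tests assert.
* **Refit.** `fit_permeability_law()` is a Levenberg–Marquardt
  least-squares fit with any coefficient subset free.  The default
  objective is relative residuals; a log-permeability objective is
  available when the model stays positive.  For the leading-coefficient
  refits (`refit_leading_coefficients()`) the rule is: relative
  residuals whenever the law with its fixed published coefficients is
  positive at every sampled point (true for the parallel law), and
  plain linear-scale least squares otherwise (the perpendicular law,
  because of the sign change) — the only objective that remains
  well-defined across the whole sweep, and the default behaviour of the
  spreadsheet-style generalised-reduced-gradient solvers typically used
  for such fits.  With all coefficients free the parameterisation has
  an exact scale indeterminacy ($c_0$ against the bracket
  coefficients), so all-free fits are only locally identified around
  their starting values.

The default sweep samples $\mathrm{VF}_{ECS} \in \{0.15, 0.175, 0.20,
0.225, 0.25, 0.30, 0.35, 0.40, 0.50, 0.60, 0.70, 0.80\}$ — denser
below 0.40, the physiological range of brain extracellular fractions.
At the dilute end of the parallel law the printed bracket nearly
vanishes ($\mathrm{VF}_{ECS} = 0.15$), so point-wise agreement there is
ill-conditioned by construction; the cross-checks compare simulated and
closed-form values from 0.175 upward.

## Infusion solver

The imaging grid is the computational grid: a structured voxel
finite-volume method, not the tetrahedral finite elements a
CAD-meshing pipeline would use, because the inputs are voxel images
and grid-refinement studies replace mesh-sensitivity studies.

* **Pressure.** Two-point fluxes with harmonic face means of the
  normal tensor components give a symmetric positive-definite system,
  factorised once (sparse Cholesky).  Off-diagonal tensor components
  (oblique fibres) are handled by a deferred-correction iteration with
  central-difference cross gradients: exact in one solve for
  axis-aligned tensor fields, iterative otherwise, with a documented
  accuracy limitation near strong tensor jumps.  Discrete mass
  conservation — boundary outflow equals the infusion rate — holds to
  solver precision.
* **Catheter.** The sub-voxel 1 mm catheter becomes a volumetric
  source: the tip face (a disk normal to the recorded orientation) is
  sampled with a uniform-area point set and the flow $Q$ is split over
  the intersected voxels proportionally to the sample counts, so the
  source footprint converges with the grid.  The inlet delivers solute
  at rate $Q c_0$ (flux form); for outward flow this coincides with a
  fixed-concentration inlet.
* **Transport.** A conservative explicit finite-volume update:
  first-order upwind advection (default), central diffusion with
  harmonic face means plus explicit cross terms for full-tensor $D$,
  and an exact exponential factor for the loss term.  Sub-stepping
  enforces the combined advective/diffusive stability bound
  (safety factor 0.5), making the default update a convex combination
  of old values and $c_0$ — hence provably $0 \le c \le c_0$ away from
  the no-solute-flux boundary.  At the study's parameters the
  diffusion number is tiny ($D_0 t/h^2 \ll 1$ for $h \ge 0.5$ mm), so
  an implicit diffusion step would buy nothing; the fully explicit
  update was chosen for its boundedness proof and simplicity.  A van
  Leer MUSCL limiter (`limiter = "vanleer"`, with a halved step bound)
  is available when the first-order scheme's numerical diffusion
  matters, e.g. in convergence studies.  The mass budget (injected,
  decayed, stored) closes to machine precision each step and is
  logged.

## Metrics

The infusion volume is the voxel set with $c > 0.025\,c_0$.  Two
volume numbers are reported: plain voxel counting (the defining
convention) and a trilinearly interpolated subvoxel estimate that
removes most of the $O(h)$ surface-quantisation bias — the latter is
what grid-convergence studies compare.  RMSD between two models
follows the per-element-volume form over the union of the two regions
(the volumes cancel on a uniform grid but are kept for future
nonuniform grids).  The principal distribution direction is the first
PCA axis of the unweighted voxel-centre coordinates (a
concentration-weighted variant exists behind a flag, off by default);
angles compare axes, $\vartheta = \arccos|d_1\cdot d_2|$, since PCA
signs are arbitrary.  The penetration length $L_{max}$ is the
projection extent along the PCA axis plus one voxel (a tip-anchored
variant is exposed as an option).  Overlap is Jaccard
(intersection over union) with the intersection-over-smaller-volume
variant attached, since the literature uses both.  The nine-orientation
comparison statistics use standard one-sided one-sample and two-sided
paired $t$ tests with $n-1$ degrees of freedom; normality is assumed,
not re-tested.

## The phantom generator

`generate_phantom()` emulates the products of a DTI+NODDI acquisition
with known ground truth on 2 mm (default) isotropic grids: a uniform
white-matter slab with a constant fibre direction, a curved bundle
whose fibre field follows circular arcs, and a three-tissue stack
(WM/GM/CSF).  White-matter tensors are prolate with the transverse
ratio chosen analytically to hit the target FA
($FA = (1-t)/\sqrt{1+2t^2}$ for eigenvalues $(1, t, t)$), compartment
maps sum to one exactly, and optional Gaussian perturbations are
clipped back to each tissue's valid range under a fixed seed
(identical seeds give bit-identical phantoms).

What the phantoms emulate: the *containers and invariants* of real
data (grids, fraction sums, FA ranges, unit fibre fields) and
idealised microstructure.  What they do not emulate: anatomical
geometry, fibre crossing/dispersion, acquisition noise correlations,
or partial-volume mixtures.  Passing phantom tests therefore
demonstrates that the pipeline is internally correct and follows its
specified physics; it does not validate the biological accuracy of
the laws on real brains.

## Problem sizes and convergence choices

The test suite and the calibration script run at sizes chosen so the
full pipeline is exercised in minutes on one CPU: the microscale sweep
uses 128 (axial) and 160 (transverse) cells across a lattice spacing;
infusion tests use $41^3$ voxels at 0.6 mm for the direction-following
check and $26^3/52^3$ pairs for grid-refinement checks.

One convergence subtlety is worth recording.  At the study's
parameters the infusion is strongly advection-dominated, so the
concentration front at the 2.5% threshold is sharper than any
desk-scale voxel grid: successive grid halvings keep shrinking the
voxel-counted threshold volume toward the sharp-front limit
($Q\,t$ of injected fluid), and no affordable pair of grids sits in
the asymptotic 5%-per-halving band.  The grid-convergence property is
therefore demonstrated where it is meaningful: on a configuration with
an enhanced molecular diffusivity whose front spans several cells,
compared with the subvoxel volume estimator and the van Leer limiter.
The direction-following and conservation properties are asserted at
the study's actual parameters.

## Known limitations

* The permeability laws are white-matter only (aligned bundles); grey
  matter keeps a constant isotropic permeability.
* The printed perpendicular law is negative below
  $\mathrm{VF}_{ECS}\approx 0.295$, as discussed above.
* Constant-radius, parallel, rigid cylinders are an idealisation of
  axonal geometry; dispersion and polydispersity are out of scope.
* The two-point-plus-correction pressure discretization loses accuracy
  near strong jumps of strongly oblique tensors.
* First-order upwind is diffusive; use the limiter for shape-sensitive
  convergence work.
* Solute accumulates at the no-flux outer boundary if the plume
  reaches it; boundedness by $c_0$ is guaranteed away from that
  boundary (the validation set-ups keep the plume well inside).
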