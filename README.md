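# cedflow

Convection-enhanced delivery (CED) places a catheter directly into
brain parenchyma and infuses a drug under positive pressure, bypassing
the blood–brain barrier. Whether the infusate reaches the target
depends on the tissue's anisotropic hydraulic permeability: in white
matter, fluid travels far more easily along axon bundles than across
them. `cedflow` is an R toolkit for surgeons' planning-model developers
and transport-modelling researchers that predicts the infusion from
diffusion-MRI microstructure, and quantifies how much the
microstructure-aware prediction differs from the conventional
constant-permeability one.

## The model

The tissue is a rigid porous medium. Steady interstitial flow obeys
Darcy's law with a catheter source and zero pressure on the brain
surface,

```
∇·v = 0,    v = −(K/μ) ∇p,
```

and the tracer follows advection–diffusion with first-order loss
(0.01 min⁻¹) and no solute flux through the glia limitans,

```
∂c/∂t = −∇·(v c) + ∇·(D ∇c) − λ c .
```

Per voxel, the tensors are built from two diffusion-MRI products:

* **DTI** supplies the fibre frame `E` and fractional anisotropy.
  Grey matter (FA ≤ 0.23) is isotropic: `D = D₀ I`, `K = K₀ I`.
  White matter keeps the measured eigenstructure, rescaled so
  `tr(D_WM) = 3 D₀` with `D₀ = 1.54e-10 m²/s`.
* **NODDI** supplies the extracellular volume fraction
  `VF_ECS = VF_ENC + VF_Water`, which sets the white-matter
  permeability eigenvalues through closed-form fibre-bundle laws
  (φ = 1 − VF_ECS, axon radius r = 0.34 µm):

```
k∥ = r²/(2.97 φ) (−1.47 − 0.94 ln φ + 2 φ − 0.5 φ² − 0.039 φ⁴)
k⊥ = r²/(7.77 φ) (−1.56 − 1.04 ln φ + 2.05 φ − 0.5 φ²)
```

so `K_WM = E diag(k∥, k⊥, k⊥) Eᵀ`. The laws are calibrated by
homogenising creeping flow through triangular lattices of rigid
cylinders — a pipeline the package reproduces end-to-end
(`build_unit_cell()`, `solve_axial_flow()`, `solve_transverse_flow()`,
`permeability_from_darcy()`, `fit_permeability_law()`). The
conventional baseline ("dti" mode) instead uses constant
`k∥ = 6.75e-15 m²`, `k⊥ = 4.22e-16 m²` everywhere.

A finite-volume solver on the voxel grid computes pressure, velocity
and concentration; metrics compare two models' infusions (RMSD over
the union of the 2.5 %-threshold volumes, PCA principal direction and
angle θ, penetration length L_max, Jaccard overlap, t tests over the
nine standard catheter orientations). A phantom generator emulates
DTI/NODDI inputs with known ground truth, so the whole pipeline is
testable without any imaging data.

## Worked example

Infuse for 180 s at 3 µL/min into a uniform white-matter phantom with
fibres along x, with both permeability models, and compare:

```r
library(cedflow)

ph <- generate_phantom(phantom_spec("uniform_wm_slab",
                                    shape = c(21, 21, 21),
                                    voxel_size = 1, vf_ecs = 0.30,
                                    seed = 42))
cath <- catheter_spec(tip = c(10, 10, 10), orientation = c(1, 0, 0))
cfg  <- simulation_config(total_time = 180)

res_noddi <- run_case(ph$tensor, ph$fa, ph$noddi, cath, cfg, mode = "noddi")
res_dti   <- run_case(ph$tensor, ph$fa, ph$noddi, cath, cfg, mode = "dti")

summary(res_noddi)
#> CED simulation summary (mode = noddi )
#>   infusion volume: 31 mm^3 in 31 voxels
#>   principal direction: (1.000, 0.000, 0.000)
#>   Darcy mass balance error: 1.21e-14
#>  time fluid_injected injected      decayed         mass residual_rel
#>   180          9e-09  4.5e-06 6.719945e-08 4.432801e-06 1.317607e-15

str(compare_results(res_dti, res_noddi))
#> List of 9
#>  $ rmsd       : num 0.045
#>  $ direction_A: num [1:3] 1 0 0
#>  $ direction_B: num [1:3] 1 0 0
#>  $ theta_deg  : num 0
#>  $ L_max_A    : num 9
#>  $ L_max_B    : num 11
#>  $ overlap_pct: num 82.9
#>  $ volume_A   : num 33
#>  $ volume_B   : num 31
```

Reading the numbers: the mass budget closes to machine precision
(9 µL of fluid and Q·c₀·t = 4.5 µmol of tracer injected over 180 s,
minus first-order loss); the infusion elongates along the fibre axis
(principal direction x in both models, θ = 0 on this symmetric
phantom); the two permeability models disagree by 4.5 % RMSD of c₀,
2 mm of penetration length, and 17 % of the involved volume even on a
homogeneous phantom. On anatomically varying fields the differences
grow and can be explored per orientation with
`nine_orientation_suite()`.

A thin command-line front end wraps the same functions:

```sh
ced phantom --scenario uniform_wm_slab --seed 42 --out ph/
ced simulate --phantom ph/ --mode noddi --tip 10,10,10 --out out/
ced compare outA/concentration.nii.gz outB/concentration.nii.gz --out report.json
```

(`ced` lives at `system.file("cli/ced", package = "cedflow")`.)

## Package layout

* `R/volume.R`, `R/noddi.R`, `R/eigen.R` — NIfTI containers, NODDI
  reparameterisation, tensor eigendecomposition, FA.
* `R/segment.R`, `R/constants.R`, `R/permlaw.R`, `R/tensors-build.R` —
  tissue classification and tensor-field construction.
* `R/unitcell.R`, `R/microflow.R`, `R/sweep.R` — the microscale
  permeability homogenisation and law fitting.
* `R/catheter.R`, `R/pressure.R`, `R/transport.R`, `R/runcase.R` —
  the CED solver and orchestration.
* `R/metrics.R` — infusion-shape and comparison metrics.
* `R/phantom.R` — synthetic ground-truth phantoms.
* `vignettes/ced-modelling.Rmd` — the methods vignette (model,
  assumptions, numerical choices, limitations).
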