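# aortasph

Particle-based mechanics of lamellar damage in the murine aortic wall.

Aortic dissection associates with medial degeneration: fragmented elastic
lamellae, dysfunctional or apoptotic smooth muscle cells (SMCs), and
localized pools of glycosaminoglycans (GAGs) replacing lost cells and
collagen.  Studying how such micro-scale defects redistribute wall stress
requires a model that resolves the individual layers of the media rather
than a homogenized continuum.  `aortasph` implements a total-Lagrangian,
corrected-kernel smoothed particle hydrodynamics (SPH) solver for nonlinear
solids, specialized to a cross-sectional, multi-layered model of the mouse
descending thoracic aorta: six elastic lamellae, five intra-lamellar
SMC/collagen layers, and an adventitia, in a rotationally periodic sector.
It is aimed at vascular biomechanics researchers who want a scriptable,
desk-scale tool for lamellar-damage and GAG-pooling experiments.

## Model core

* Discrete operators: Spiky kernel `ξ(R) = 10(h−R)³/(πh⁵)`, gradient
  correction matrices `A_i = Σ_j V_j ∇ξ(R_j) ⊗ R_j` for first-order
  completeness, per-particle deformation gradients
  `F_i = Σ_j r_j ⊗ V_j Ã∇ξ(R_j)`, internal forces
  `f_i = Σ_j V_i V_j (P_i Ã∇ξ_i − P_j Ã∇ξ_j)`, hourglass penalty and
  viscous stabilization, damped leapfrog relaxation to quasi-static
  equilibrium.
* Constitutive model (constrained mixture, in vivo reference with
  deposition prestretches): per particle
  `W = φ^e[ μ/2 (I₁^e − 3) − μ ln J + λ̂/2 (ln J)² ]
  + Σ_k φ^{c_k} c₁/(4c₂) (exp[c₂(I₄^k − 1)²] − 1)`,
  with tension/compression branch switching on `I₄^k`; parabolic active
  SMC stress `σ_θ^act = φ^{c₂} T_max λ_θ [1 − ((λ_max−λ_θ)/(λ_max−λ_min))²]`;
  GAG pools `σ = μ^GAG(B − I)/J − RT(√(c_FC² + c*²) − c*) I`.
* Damage protocols: severance of lamellar segments by neighbour-list
  surgery (stress drops identically to zero), and the staged
  SMC-to-GAG-pool replacement (loss of contractility → stiffness
  reduction → Gibbs–Donnan swelling → rupture of the bounding lamellae),
  with regional maximum-stress read-outs.

The luminal pressure is an output of displacement control
(`P = σ̄_θ h / r_in`); pressure targets are met by secant iteration on the
inner radius.  See the methods vignette
(`vignettes/aortasph-methods.Rmd`) for assumptions, parameters and
numerical choices.

## Worked example

```r
library(aortasph)

wall  <- build_wall(wall_geometry(sector_deg = 15), density = 0.24)
model <- sph_model(wall, control = stabilization_params(
  cfl = 0.4, tol_ke = 1e-5, tol_f = 5e-4))

model <- set_reference(model)     # prestretched in vivo state
model$record
#> <equilibrium_record> P = 101.9 mmHg (13.59 kPa), outer diameter 1374.1 um
#>   r_in 646.8, thickness 40.23, lambda_theta 1, tone 0 [converged, 2650 steps]

active <- equilibrate_at(model, pressure = 102, active = TRUE)
active$record
#> <equilibrium_record> P = 101.9 mmHg (13.59 kPa), outer diameter 1040.9 um
#>   r_in 466.04, thickness 54.41, lambda_theta 0.7396, tone 1 [converged, 2850 steps]

100 * (model$record$outer_diameter - active$record$outer_diameter) /
  model$record$outer_diameter
#> [1] 24.25
```

The deposition prestretches alone put the relaxed lattice at the
homeostatic pressure (101.9 mmHg vs the 102 mmHg operating point), and
maximal SMC tone at fixed pressure constricts the outer diameter by ~24%
— the vasoconstriction response the active parameters encode.  Damage
experiments chain onto such states, e.g.

```r
damaged <- disrupt_lamella(active, locate_lamella(active, 0.4)$lamella,
                           extent_deg = 2)
regional_max_stress(damaged, "layer", 4, 6, 9)   # kPa, near the defect
```

`run_scenario()` scripts the full staged protocols (sequential rupture,
single / radially stacked / merged GAG pools) into tidy tables, and
`write_vtk()` / `write_particles_csv()` export particle fields.

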