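---
title: "Methods: a particle model of lamellar damage in the aortic wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a particle model of lamellar damage in the aortic wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`aortasph` simulates an idealized cross-section of the murine descending
thoracic aorta as a two-dimensional annular sector of particles under a
fixed axial stretch, using a total-Lagrangian, corrected-kernel smoothed
particle hydrodynamics (SPH) discretization for nonlinear solids.  The wall
is explicitly multi-layered: six elastic lamellae (thin, elastin-dominated
rings, group `M_el`), five intra-lamellar layers of smooth muscle cells
(SMCs), fibrillar collagen and diffuse glycosaminoglycans (group `M_int`),
and a collagen-dominated adventitia (group `A`).  The purpose of the
explicit layering is to study *damage*: severing segments of individual
lamellae, switching off SMC contractility, and replacing intra-lamellar
pools by osmotically swelling GAGs — and to read out the resulting
redistribution of circumferential stress onto the neighbouring layers.

Key modelling assumptions:

* **In vivo reference.** The kinematic reference is the loaded homeostatic
  state (102 mmHg, axial stretch 1.62), not an excised, unloaded state.
  Each constituent carries a *deposition prestretch* (constrained-mixture
  concept): elastin a diagonal tensor `G^e = diag(0.32, 1.90, 1.62)`
  (radial, circumferential, axial), SMC/collagen families scalar
  prestretches (1.20 circumferential SMC+collagen, 1.25 otherwise).  With
  `F = I` at the reference, the mixture is prestressed and the wall carries
  the homeostatic pressure, which the package verifies through the Laplace
  relation `P = sigma_theta * h / r_in`.
* **Plane problem.** Only the cross-sectional (r, theta) motion is solved;
  the axial stretch is fixed at 1 relative to the prestretched reference
  (the in vivo 1.62 lives inside the prestretches).  The axial stress
  component is evaluated and reported but never enters the in-plane force
  balance.
* **Quarter symmetry.** A sector with rotational-periodic boundary images
  stands in for the full circumference.  Any sector angle dividing 360° is
  supported; the scaled-down studies below use 8–30° sectors, which is
  legitimate because the defects studied are local (a few degrees wide)
  and the healthy response is axisymmetric.
* **Quasi-statics.** Masses are fictitious; equilibria are found by damped
  explicit dynamics (dynamic relaxation).  Only converged states are
  interpreted.

## Constitutive model

Per particle the strain energy is a mass-fraction-weighted mixture

* elastin: modified neo-Hookean,
  `phi_e [ mu/2 (I1e - 3) - mu ln J + lambda_hat/2 (ln J)^2 ]`, with
  `I1e = tr((F G^e)^T F G^e)` and `J = det(F_2D) * lambda_z` the particle
  volume ratio.  `mu = 89.71` kPa; `lambda_hat = 1000 mu` enforces
  near-incompressibility.  The volumetric terms penalize the *particle*
  volume change (not an elastin-specific one), so the lamellae are the
  stiffest, most nearly isochoric component.
* four fiber families (axial, circumferential, two symmetric diagonals at
  ±29.91° from the axial direction), each an exponential
  `c1/(4 c2) (exp[c2 (I4-1)^2] - 1)` in the squared total fiber stretch
  `I4 = G_k^2 (C : M^k x M^k)`.  Tension (`I4 >= 1`) and compression
  branches use different constants — compressed fiber networks, supported
  only by the surrounding GAG matrix, are much softer.  At `I4 = 1` both
  branches give zero fiber stress, so the switch is continuous.  The SMC
  passive response is folded into the circumferential (k = 2) medial
  family.

One extraction note: in the parameter table the medial SMC+circumferential
collagen row is typographically ambiguous between
(`c1- = 249.5`, `c2+ = 0.24`) and (`c1- = 49.5`, `c2+ = 0.242`).  The
package defaults to the latter: a compression stiffness far below tension
matches the stated physical intent and mirrors the ~8x tension/compression
ratio of the diagonal families.  Both constants are plain entries of
`wall_materials()` and can be overridden.

Active SMC tone adds a circumferential Cauchy stress with a parabolic
length-tension relation, `phi_c2 Tmax lambda_theta [1 - ((lmax -
lambda_theta)/(lmax - lmin))^2]` with `Tmax = 500` kPa, `lmax = 1.1`,
`lmin = 0.6`, zero outside `[lmin, lmax]`.  The stretch is measured with
respect to the passive reference; the stress acts along the *current*
circumferential direction of the particle (the configuration-consistent
choice during large constriction) and is mapped into the first
Piola-Kirchhoff stress as `P_act = J sigma_act F^{-T}`.

GAG-pool particles use `sigma = mu_gag (B - I)/J - pi I` with
`mu_gag = 0.1` kPa and, once swelling is activated, a Gibbs-Donnan osmotic
pressure `pi = R T (sqrt(cFC^2 + cstar^2) - cstar)` with `cFC = 200`,
`cstar = 300` mEq/l and `T = 310` K, i.e. 156.1 kPa.  The swelling term is
deformation-independent; in particular the fixed-charge concentration is
*not* diluted as the pool inflates, following the stated model form.

## Discretization

The Spiky kernel `xi(R) = 10 (h-R)^3 / (pi h^5)` weights neighbour
interactions within a support `h`.  The support is a free numerical
parameter (the physical inputs fix only the particle density); the default
is `h = 3 x` the nominal particle spacing, which gives 20–30 neighbours in
2D.  A per-particle correction matrix `A_i = sum_j V_j grad xi (x) R_j`
restores first-order completeness: corrected gradients reproduce affine
deformation fields exactly (to 1e-13 in the test suite), including at the
wall surfaces, which is why no special boundary treatment is needed.  Two
discrete caveats, both regression-tested: (i) the raw kernel sum
`sum_j V_j xi(R_j)` overshoots unity by ~8% at the default support (the
midpoint-type lattice sum of a convex kernel), falling below 5% only for
`h >= ~4.2 x` spacing — harmless here because all mechanics flow through
the corrected gradients; (ii) at the periodic sector edges only
deformations commuting with the sector rotation (scalings/rotations, i.e.
the axisymmetric motions actually encountered) are represented exactly.

The lattice is deterministic (no random number generator anywhere in the
core): concentric rings, one ring per lamella by default (`lamella_rings =
2` is available), the intra-lamellar gaps filled with 2/3/4 rings at
densities 0.24/0.39/0.62 per um^2, and the adventitia with rings of equal
spacing.  Arc spacing per ring is chosen so each particle's Voronoi-like
ring-sector area equals `1/density`; particle volumes tile the sector area
exactly.  Lamellar radii equally partition the media, which reproduces the
three quoted lamellar radii (657, 663, 668 um) to within a ring spacing.

## Dynamic relaxation

Forces are the SPH divergence of the first Piola-Kirchhoff stress
(pairwise antisymmetric), an hourglass penalty on the deviation of each
pair from the locally affine motion (control parameter `alpha = 25`,
penalty stiffness `E` at the elastin modulus scale), and a viscous
stabilization stress `P_visc = 2 eta J d F^{-T}`.  Integration is damped
leapfrog with:

* **Stiffness-proportional mass scaling.** Each particle's fictitious
  density is proportional to a pessimistic local tangent-stiffness bound
  (floor 1/16), equalizing the local critical time step between the
  near-incompressible lamellae and the much softer intra-lamellar tissue.
  With masses fictitious this changes nothing about the converged states
  and shortens relaxations several-fold.
* **Velocity cap.** Per-step displacements are capped at 0.15 x spacing,
  which rides out transient stiffening of the exponential fibers without
  element inversion; it is inactive near equilibrium.
* **Damping.** Global velocity scaling (0.995/step) plus kinetic damping
  (velocities zeroed when the kinetic energy passes a peak).  The scaling
  is disabled once the kinetic-energy ratio is within 4x of the
  convergence threshold, so converged states are governed by force balance
  alone; insensitivity of converged stresses to a 2x change in `eta`
  (< 0.5%) is part of the test suite.
* **Convergence.** Kinetic energy below `tol_ke` of its peak *and* maximum
  residual force below `tol_f` of the mean internal force scale.  Package
  defaults are 1e-6 / 1e-4; the study configurations in the tests and the
  acceptance script use 1e-5 / 5e-4, validated by the eta-insensitivity
  and force-balance (Laplace vs constraint reaction, < 5%) checks.
* **Boundary conditions.** Inner-rim particles are projected onto a
  prescribed radius (ramped smoothly); the outer rim is traction-free;
  sector edges are periodic.  Pressure is an *output* (semi-inverse
  method): the Laplace relation applied to the volume-weighted mean
  circumferential Cauchy stress, current thickness and inner radius.
  Pressure targets are met by secant iteration on the inner radius, seeded
  by a homogenized thin-wall inverse, with every new target preceded by an
  incompressible-annulus remap of the whole lattice (a near-equilibrium
  initial guess that keeps relaxations to a few thousand steps).

The thin-wall oracle used for seeding and validation homogenizes the
constituent specifications with the lattice's volume fractions under
incompressible membrane kinematics and closes the force balance with the
mean radial stress of a pressurized thin wall (`-P/2`); it tracks the
particle model's pressure-diameter curve within 5% over 80–190 mmHg.

## Damage protocols

*Lamellar disruption* follows three numbered steps: (i) the segment's
particles lose their strain energy (`mu`, `lambda_hat` set to zero);
(ii) they are removed from every neighbour list; (iii) intact particles of
the same lamella on opposite sides of the gap are severed from each other
(complete disconnection; this matters only when the gap is narrower than
the kernel support, and is tested at such an extent).  Correction matrices
are rebuilt after every surgery, and a relaxation dissipates the released
elastic energy.  Disrupted particles are frozen with exactly zero stress.

*SMC-to-GAG replacement* is staged per pool of intra-lamellar particles:
step I removes the pool's active stress only; step II replaces the
mixture by the GAG material; step III switches on the osmotic pressure
(ramped during its relaxation); step IV ruptures the bounding (or, for
radially stacked pools, the interior) lamellae over the pool's extent.
Steps must be applied in order, and several pools are stepped together.

Scenario geometry decisions (the source text constrains these only
loosely):

* Damage runs use full smooth-muscle tone.  This is not optional: the
  loss-of-contractility step must change the state, and the observed
  pressure dependence of the stiffness-reduction step (negligible effect
  at 102 mmHg, marked at 184 mmHg) emerges precisely because the
  constricted 102 mmHg state puts the pool's circumferential family on its
  soft compression branch.
* The default single pool occupies the layer between the middle and
  next-outer lamellae; defects are centred on the sector midline,
  maximizing distance from the periodic edges.
* "Two pools separated by an intact intra-lamellar space" is implemented
  as *radial* stacking (layers `band-2` and `band`, one intact layer
  between): the interior/exterior lamella terminology, the merged variant
  (shared lamella of *adjacent* layers removed, pool extents doubled), and
  the pressure dependence of pool interaction (the thinner high-pressure
  wall brings the pools closer) all point to radial, not angular,
  separation.
* Regional read-outs take the maximum circumferential Cauchy stress over a
  lamella or layer within the defect's angular window extended by one
  kernel support, excluding particles within one support of a
  disrupted-segment end, where collocation stresses at the "tip" are not
  trusted.

## Problem sizes and what the tests show

The full quarter-sector at density 0.24/um^2 is ~10,100 particles.  The
package's studies run on reduced sectors chosen so that defects stay
several kernel supports away from the periodic images: 8° for operator
checks, 10° for the density-robustness comparison (0.24 vs 0.62/um^2),
15° for the reference, activation and pool/rupture scenarios.  Because the
lattice, the material model and the solver are identical at every sector
angle and density, and because the healthy-state observables are
axisymmetric, these configurations exercise the same code paths as the
full-circumference model; what they cannot show is interaction between
*distant* defects around the circumference.

Other known limitations: no fluid-structure interaction or transmural
transport; no growth, remodelling, or mechanosensing; damage is prescribed
by scenario, never triggered by a failure criterion; transient dynamics
are not physical (masses fictitious); and stresses within one kernel
support of a severed segment end are excluded from read-outs rather than
interpreted.  Quantitative stress-concentration *levels* after GAG
swelling are sensitive to discretization details of the thin lamellae
(single- vs double-ring lamellae, kernel support, pool placement); the
package therefore treats ordering and trend statements (concentration
grows with pressure, falls with defect size; merged pools > stacked
pools > single pool) as the robust outputs, and those are what the test
suite asserts quantitatively against the solver's own converged states.
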