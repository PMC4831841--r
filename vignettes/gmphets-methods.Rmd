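---
title: "Growing porohyperelastic tissue with transport: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing porohyperelastic tissue with transport: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmphets)
```

## The model

`gmphets` simulates a fully saturated porous hyperelastic solid permeated
by an interstitial fluid that carries a dissolved neutral species, and lets
that mixture *grow*: solid (or solid plus fluid) mass is created in place,
driven by time, by the local species concentration, or by the local
effective stress. The intended application is soft-tissue growth and
remodelling — the built-in scenarios model a coronary-artery wall as a
plane-strain annulus under intraluminal pressure.

### Mixture mechanics

The primary fields, all nodal, are the displacement $\mathbf u$, the fluid
potential $\tilde\mu^{f*}$ and the chemical potential $\tilde\mu^{c*}$.
Pore pressure $p^f$ and concentration $c$ are secondary, recovered at each
Gauss point from the standard mechano-chemical potentials

$$\tilde\mu^{f*} = p^f + p_0^o - \bar R\theta\,\phi^c c, \qquad
  \tilde\mu^{c*} = \mu_0^c + \bar R\theta \log(\gamma^c_{mat}\, c),$$

which invert in closed form. Using potentials rather than $(p^f, c)$ keeps
the primaries continuous across material interfaces where a partition
coefficient (a ratio of activity coefficients) imposes a concentration
jump: at equal chemical potential, the material-side concentration is
`c_bath / partition`. The datums $p_0^o$ and $\mu_0^c$ are arbitrary
baselines; the package sets $p_0^o = 0$ and derives $\mu_0^c$ from a floor
concentration one tenth of the smallest boundary-equilibrium concentration
of the problem. Any consistent choice shifts both potentials uniformly and
cancels in every gradient; a test asserts that solutions are invariant
under datum shifts to solver accuracy.

Stress splits by the effective stress principle,
$\mathbf S = \mathbf S^{\mathrm{eff}} - J \mathbf C^{-1} p^f$, with the
effective part carried by the solid skeleton. The skeleton is compressible
Neo-Hookean,

$$\mathbf S^{\mathrm{eff},e} = (\lambda \ln J^e - \mu)\,\mathbf C_e^{-1}
 + \mu \mathbf I,$$

with $(\lambda, \mu)$ derived from the $(C_{10}, D_1)$ pair
($\mu = 2C_{10}$, $\kappa = 2/D_1$, $\lambda = \kappa - \tfrac23\mu$).

### Volumetric growth

Growth enters through the multiplicative split
$\mathbf F = \mathbf F^e \mathbf F^g$ with isotropic
$\mathbf F^g = \vartheta\,\mathbf I$; $\vartheta > 1$ is growth,
$\vartheta < 1$ resorption. The elastic stress is evaluated on
$\mathbf C_e = \mathbf C / \vartheta^2$ and pulled back as
$\mathbf S^{\mathrm{eff}} = \mathbf S^{\mathrm{eff},e} / \vartheta^2$.
Created mass appears in the conservation equations as volumetric sources:
the fluid balance gains $-3\vartheta^2\dot\vartheta$ and the species
balance $-3\bar\rho^s \vartheta^2\dot\vartheta\, c$, where
$\bar\rho^s = \rho_0^{s*}/\rho_T^s$ is the normalised solid growth density:
1 when only solid is added at its true density, $1 - n_0$ when solid and
fluid are added together at their initial apparent densities. True
densities never appear in the discrete equations — only $\bar\rho^s$ does —
so they are not inputs.

Porosity after growth and deformation is
$n = 1 - J^{-1}[(1 - n_0) + \bar\rho^s(\vartheta^3 - 1)]$. The porous-media
model is only meaningful for $0 < n < 1$, which bounds the growth stretch
between $[1 + (n_0 - 1)/\bar\rho^s]^{1/3}$ and
$[1 + (J - 1 + n_0)/\bar\rho^s]^{1/3}$. The solver traps any violation and
aborts with the offending element; for the unbounded time-linear law the
closed-form limiting time (about 181 s for the rigid solid-only benchmark)
is available as `limiting_growth_time()` and through the CLI `check`
subcommand.

Three growth laws are implemented:

* **time-linear**: $\dot\vartheta = \alpha$, updated exactly;
* **concentration**: $\dot\vartheta = k_\vartheta(\vartheta)(c - c_{thresh})$;
* **stress**: $\dot\vartheta = k_\vartheta(\vartheta)\,\mathrm{tr}\,
  \mathbf M^{\mathrm{eff},e}$, the driver being the trace of the effective
  elastic Mandel stress $\mathbf C_e \mathbf S^{\mathrm{eff},e}$ (the
  quantity energy-conjugate to the growth velocity gradient).

The nonlinear laws use the Lubarda–Hoger limiter
$k_\vartheta = \tau_\pm^{-1}\big((\vartheta^{max/min} -
\vartheta)/(\vartheta^{max/min} - 1)\big)^{\gamma_\pm}$ (growth branch for a
positive driver, resorption branch for a negative one), which drives the
rate to zero as $\vartheta$ approaches its bounds.

### Transport

Fluid and species fluxes follow the coupled Onsager (generalised
Darcy/Fick) form with Lagrangian mobilities
$\tilde L^{ff} = J\mathbf C^{-1} k^{ff}$,
$\tilde L^{fc} = \tilde L^{cf} = J\mathbf C^{-1} k^{ff} b^{fc} c$ and
$\tilde L^{cc} = J\mathbf C^{-1}\,[c\,d^{cc}/(\bar R\theta) +
c^2 k^{ff} (b^{fc})^2]$. The $1/(\bar R\theta)$ scaling of the diffusive
mobility is required dimensionally (a molar flux against a molar-energy
gradient) and makes the dilute-limit species flux exactly Fick's law
$-d^{cc}\nabla c$; it also produces a species transient on the multi-hour
scale of the arterial runs, which is what separates the two diffusivity
regimes of the concentration-driven scenario. A Péclet-like number
$\beta = k^{ff} b^{fc} / d^{cc}$ is echoed with every run; multiplied by
the driving pressure drop it is ≈3.5 for the experimental diffusivity
(convection-shaped concentration field) and ≈0.035 for the 100-fold larger
diffusivity (diffusion-dominated).

## Discretisation

Three-noded linear axisymmetric triangles with a single Gauss point at the
centroid; primaries are interpolated linearly and continuous, secondaries
are piecewise constant per element, as is $\vartheta$. The annular wall is
meshed as a strip one quad thick in $Z$, each quad split along a consistent
diagonal (so $n$ radial subdivisions give $2n$ elements, matching the 120 /
320 / 160-element meshes of the benchmarks). The axisymmetric volume weight
$2\pi R_c A$ at the centroid integrates the straight-sided strip exactly,
and the discrete axisymmetric Piola identity holds, so a uniform pore
pressure produces no spurious interior forces.

Every tensor at a Gauss point carries the axisymmetric block structure
(in-plane 2×2 block plus a hoop component), so the assembly stores only the
independent components as vectors over all elements and evaluates the
constitutive formulas in closed component form — the whole residual and
tangent assembly is vectorised across elements, with one sparse
scatter per Newton iteration.

Plane strain is imposed by fixing every axial displacement; the rigid
validation problem fixes all displacements. The intraluminal pressure acts
twice, as the benchmark scenarios require: as a follower traction on the
current inner radius (load stiffness deliberately omitted — displacements
stay below 2% of the radius and Newton convergence is unaffected) and as
the pore-pressure Dirichlet value on the inner face; the outer face is
traction-free at zero pore pressure. Species boundary values are the
bath-equilibrated material-side concentrations and are held from the first
step; the interior starts at the outer-boundary value.

### Time stepping and the nested Newton loop

Each step solves the backward-Euler form of the three conservation laws
(rates are first-order backward differences, and
$J\mathbf C^{-1}\!:\!\dot{\mathbf E} \equiv \dot J$ is used exactly).
The step starts from the previous converged state with the new boundary
values injected — a deliberate simplification relative to a forward-Euler
predictor: the backward-Euler corrector defines
the converged state either way, and Newton from the previous state is
robust at the step sizes used. Within each global iteration:

1. every element updates $\vartheta$ at fixed total deformation — exactly
   for the time-linear law, otherwise by a bracketed Newton/bisection
   iteration on the local backward-Euler residual
   $R_\vartheta = \vartheta - \vartheta_n - \Delta t\,
   k_\vartheta(\vartheta)\,\phi^g(\vartheta)$ to $|R_\vartheta| < 10^{-12}$
   (the bracket $[\vartheta^{min}, \vartheta^{max}]$ always contains a
   root because $k_\vartheta$ vanishes at the bounds);
2. stresses, fluxes, sources and the consistent tangent are reassembled;
   the tangent includes the geometric and material stiffness, the
   transport-coefficient state dependence, and the sensitivity of the
   converged growth stretch to strain (stress law) or concentration
   (concentration law) via the implicit function theorem on
   $R_\vartheta$ — without this coupling term the stress-driven iteration
   contracts only linearly and can exceed the iteration cap;
3. one global Newton solve updates the primaries.

The secondary residual of the original bookkeeping is identically zero
here because pore pressure and concentration are recovered in closed form
from the interpolated potentials; `assemble()` reports it as such.

Numerical safeguards, all of which are exercised by the test suite:

* the linear systems are solved by sparse LU after symmetric diagonal
  equilibration (the displacement, fluid and species blocks differ by
  ~20 orders of magnitude in scale);
* the Newton increment of the chemical potential is clamped to
  $\pm 2\bar R\theta$ per iteration, because the concentration is
  exponential in it — without the clamp the first load step can overshoot
  to unphysical concentrations;
* convergence is judged blockwise: each field's residual must fall below
  $10^{-8}$ of its own running reference, or to the cancellation floor of
  the assembly (measured against the gross, unsigned element
  contributions), or the increments must drop below $10^{-10}$ relative
  with physically meaningless absolute floors ($10^{-15}$ m,
  $10^{-5}$ Pa, $10^{-6}$ J/mol); a stalled iteration already four orders
  below its reference is accepted as floor-limited. At most 25 global
  iterations, after which the step aborts with a step-failure error
  (usually meaning the step is too large).

## Validation against closed forms

For the internally pressurised *rigid* cylinder with time-linear growth the
fluid equation reduces at each instant to a quasi-static Poisson problem,
$(1/r)(r\,p^{f\prime})' = -3(1+\alpha t)^2\alpha / k^{ff}$ with the
pressures pinned at the faces, solved by
$p^f = -(s/4k^{ff})r^2 + A\ln r + B$; with $\alpha = 0$ this is the
consolidated logarithmic profile, whose value at the geometric-mean radius
is exactly half the driving pressure. The effective stress is spatially
homogeneous, $[-3\lambda\ln\vartheta + \mu(\vartheta^{-2}-1)]\,\mathbf I$,
and the porosity follows $n = n_0 - \bar\rho^s(\vartheta^3 - 1)$. The
acceptance suite requires the finite element solution to track the
pressure and stress within 1% in the maximum norm at every output time of
the 150 s growth phase, and the porosity to match exactly, for both the
solid-only and solid/fluid sources — whose primary histories are
identical, differing only in porosity.

## What the scenarios do and do not show

The preset scenarios reproduce the three published arterial benchmarks:
time-driven growth of a rigid cylinder validated against the closed forms;
stress-driven growth comparing a hyperelastic and a porohyperelastic wall
(320 elements, 5 load steps + 1 consolidation + 1000 growth steps at
$\Delta t = 50$ s, producing the pre-growth Mandel-stress range of roughly
72–112 kPa and its relaxation to ~7.4 kPa); and concentration-driven
growth/resorption at two diffusivities (160 elements, 2000 growth steps).
The acceptance checks on the concentration scenario are qualitative
pattern checks (inner growth, outer resorption, thickness ordering of the
two Péclet regimes) and are run on a coarser mesh (80 elements) with the
same 10^5 s horizon at $\Delta t = 125$ s, sizes at which the orderings are
stable.

These are idealised plane-strain, isotropic, single-species problems with
constant Eulerian transport parameters. Passing them demonstrates the
correctness of the coupled formulation and its implementation, not
fidelity to any particular tissue: anisotropic growth, remodelling of
material properties, strain-dependent permeability, charged species and
osmotic swelling ($\phi^c \ne 0$ scenarios — the formulas are implemented
and tested, but no benchmark exercises them) are out of scope.

## Known limitations

* Low-order elements: piecewise-constant secondaries need the published
  mesh densities for smooth stress profiles; nodal averaging of
  Gauss-point values is the intended presentation.
* The split diagonal of the strip mesh breaks exact top/bottom symmetry,
  so results depend on the (physically immaterial) strip height at the
  discretisation-error level (~0.1% at 20 elements); the default height is
  0.025 mm.
* Fixed time steps; a failed step reports its residual but is not retried
  with a smaller $\Delta t$.
* The follower-pressure load stiffness is omitted from the tangent (small
  displacements; quadratic convergence is retained in practice).

## A short session

```{r example, eval = FALSE}
cfg <- scenario_config("rigid-time")
run <- run_scenario(cfg)
run
write_outputs(run, "out/rigid-time", format = c("csv", "vtk"))

spec <- rigid_cylinder_spec()
limiting_growth_time(spec)         # ~180.9 s
rigid_pf_profile(spec, t = 150)    # closed-form pressure profile
```
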