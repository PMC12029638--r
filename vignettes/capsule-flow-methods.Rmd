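---
title: "Methods: immersed-boundary lattice Boltzmann simulation of cells and carriers in microvessel flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immersed-boundary lattice Boltzmann simulation of cells and carriers in microvessel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemolbm)
```

## The model

`hemolbm` simulates deformable particles — red blood cells (RBCs) and
micrometric drug carriers (DCs) — suspended in pressure-driven flow through
a microvessel of around 50 µm diameter. Blood plasma at this scale is
treated as an incompressible Newtonian fluid (density 1050 kg/m³, dynamic
viscosity 1.2 mPa·s); the particles are closed elastic membranes filled
with fluid of the same density and viscosity.

Three coupled ingredients make up the solver.

**Fluid: D3Q19 LBGK.** The Navier–Stokes equations are solved with the
single-relaxation-time (BGK) lattice Boltzmann method on a uniform grid
with nineteen discrete velocities. Each step relaxes the populations
$f_i$ toward the second-order Maxwell–Boltzmann equilibrium

$$f_i^{eq} = \rho\, w_i \left[ 1 + \frac{\mathbf e_i\cdot\mathbf u}{c_s^2}
 + \frac{(\mathbf e_i\cdot\mathbf u)^2}{2 c_s^4}
 - \frac{\mathbf u^2}{2 c_s^2} \right], \qquad c_s^2 = \tfrac13,$$

with relaxation time $\tau$ tied to the kinematic viscosity by
$\nu = (\tau - \tfrac12) c_s^2$ (lattice units). External and
fluid–membrane forces enter through the Guo forcing scheme: the
trapezoidal half-force shift $\rho\mathbf u = \sum_i \mathbf e_i f_i +
\tfrac12\mathbf F$ together with the $(1 - \frac{1}{2\tau})$-weighted
per-direction source. The equilibrium is evaluated at the force-corrected
velocity; this pairing is what makes the scheme second-order accurate in
the forcing, and it is also why a uniform body force accelerates a uniform
fluid by exactly $a$ per step (one of the unit tests). Walls are voxelized
and handled by halfway bounce-back; moving plates add the Ladd momentum
correction $2 w_i \rho\, \mathbf e_i \cdot \mathbf u_w / c_s^2$. The
pressure drop that drives vessel flow is realised as the equivalent
uniform body acceleration $a_x$ with periodic ends
($\Delta p = \rho a_x L$), which avoids maintaining two competing inlet
conditions.

**Membranes: triangulated capsules.** Each particle is a closed triangle
mesh (RBC: biconcave discocyte, 480 faces; DC: icosphere, 120 faces; both
satisfy Euler's closure $N = N_f/2 + 2$). The total elastic energy is

$$E = E_S + E_B + E_A + E_V$$

with

* Skalak in-plane strain energy
  $E_S = \sum_i A_i^0\,\varepsilon_s(I_1, I_2)$,
  $\varepsilon_s = \frac{\kappa_s}{12}(I_1^2 + 2 I_1 - 2 I_2)
  + \frac{\kappa_\alpha}{12} I_2^2$, where
  $I_1 = \lambda_1^2 + \lambda_2^2 - 2$ and
  $I_2 = \lambda_1^2\lambda_2^2 - 1$ come from the principal stretches of
  the per-face 2-D deformation gradient (reference triangle stored in its
  own plane; stretches from the singular values of the 2×2 map). The
  reference (undeformed) face areas weight the sum.
* Bending $E_B = \frac{\kappa_B}{2}\sum_{\text{edges}}
  \tan^2\!\big(\tfrac{\theta - \theta^0}{2}\big)$ over signed dihedral
  angles between adjacent face normals, with rest angles taken from the
  constructed shape (a sphere is bending-stress-free while spherical). The
  tangent half-angle form stiffens sharply toward a crease; the plain
  quadratic $\frac{\kappa_B}{2}\sum(\theta-\theta^0)^2$ is selectable
  (`bending_form = "quadratic"`) and is used in the migration experiment,
  where deep transient folds would otherwise hit the tangent singularity.
* Global constraints $E_A = \kappa_A (A - A_0)^2 / (2 A_0)$ and
  $E_V = \kappa_V (V - V_0)^2 / (2 V_0)$. These dimensional forms are the
  ones consistent with the moduli units (N/m and N/m²; both energies are
  then in joules).

Nodal forces are the exact analytic gradient $-\partial E/\partial
\mathbf x_n$, computed in compiled code and verified in the test suite
against central finite differences of the energy to better than $10^{-5}$
relative, term by term. Translation and rotation invariance of every term
(zero net force and torque) are asserted separately.

**Coupling: two-point immersed boundary.** Forces spread to the grid and
velocities interpolate back through the tensor-product hat kernel
$\phi(r) = 1 - |r|$ on a 2×2×2 support. The kernel is a partition of
unity, reproduces linear fields exactly, and makes spreading and
interpolation exact adjoints — all asserted in tests. One coupled cycle is
membrane forces → spread → collide/stream/bounce-back → interpolate →
forward-Euler node advection. Mesh coordinates are kept unwrapped;
periodic wrapping happens inside the transfer kernels so membranes never
tear across the boundary.

## Units

Lattice spacing, time step and density are 1 in lattice units; every
physical quantity converts through powers of $\Delta x$, $\Delta t$,
$\rho$. The reference microvessel unit system
($\Delta x = 1\,\mu$m, $\Delta t = 18$ ns) puts the relaxation frequency
at $1/\tau = 1.78$ and maps lattice velocity 0.0012 to 0.0667 m/s.
Physical moduli columns are always authoritative; lattice values are
derived, never entered by hand.

## The biconcave cell

The RBC mesh projects a unit icosphere through
$x' = Rx$, $z' = Rz$,
$y' = \operatorname{sign}(y)\,\tfrac{R}{2}\sqrt{1-r^2}\,(C_0 + C_1 r^2 +
C_2 r^4)$ with $r^2 = x^2 + z^2$ and shape constants $C_0 = 0.207$,
$C_1 = 2.003$, $C_2 = -1.123$. The scale $R$ is set to the requested
maximum (rim) radius — the radius is the stated geometric datum, no
reference volume being available — and the resulting area and volume
become the equilibrium values $A_0$, $V_0$.

## Validation cases

**Poiseuille pipe flow.** A body-force-driven straight cylinder
(default $D = L = 20$ lattice units, $\tau = 1$, peak velocity 0.05) is
run ~20 momentum-diffusion times and the diametral velocity profile is
compared with $u(r) = \frac{a}{4\nu}(R^2 - r^2)$. With even cross-section
dimensions the halfway bounce-back wall of the diametral rows sits exactly
at radius $D/2$ and the relative L2 error is below 1% (the acceptance
threshold is 2%). A caution for readers of the two printed forms of this
profile: $\frac{a}{4\nu} y (D-y)$ is the *same pipe profile* written along
a diameter with $y$ measured from the wall; the parallel-plate channel
solution is $\frac{a}{2\nu} y(D-y)$, and the plane-channel unit test uses
the latter.

**Sheared capsule.** An initially spherical capsule (radius 5) sits at the
centre of a 30³ cell whose top and bottom plates move oppositely along
$x$. For a Skalak membrane the small-strain surface shear modulus is
$G = \kappa_s/3$, so the classical first-order result
$D = \frac{25}{12}\,\mu\dot\gamma r / G$ predicts
$D/\mathrm{Ca} = 25/4 = 6.25$ with $\mathrm{Ca} = \mu\dot\gamma
r/\kappa_s$ and $\kappa_s = 4\times10^{-4}$ N/m. Choices made here, once:

* the run uses $\Delta t = 2\times10^{-7}$ s ($\tau \approx 1.19$), which
  keeps a small-Ca run at around $10^4$ steps; $D/\mathrm{Ca}$ is
  dimensionless and unit-system independent;
* unstated co-moduli: $\kappa_\alpha/\kappa_s = 0.1$ (the drug-carrier
  ratio of the parameter table, consistent with the shear-dominated
  first-order anchor), $\kappa_B = \kappa_A = 0$,
  $\kappa_V = 100$ N/m² to hold the volume (it stays within 0.2%);
* $A$ and $B$ in $D = (A-B)/(A+B)$ are the semi-axes of the vertex
  cloud's gyration-tensor ellipse in the flow–gradient plane. This
  estimator is exact for affine (ellipsoidal) deformations and robust to
  mesh-scale surface noise; reading $A,B$ as extreme extents instead gives
  values 15–25% higher on the same meshes, increasingly noise-dominated as
  Ca shrinks. The gyration convention is used consistently everywhere.

Measured steady values: $D/\mathrm{Ca} \approx 5.55$ at Ca = 0.01,
$5.33$ at 0.02, $5.01$ at 0.03 (Skalak hardening makes the ratio fall
with Ca); linear extrapolation to $\mathrm{Ca}\to 0$ gives $\approx 5.9$,
within 10% of the 6.25 anchor. These are the quantities
`scripts/acceptance.R` recomputes.

**Momentum and mass audits.** In closed domains the per-step mass change
is at round-off, and in a periodic box with an immersed capsule the
per-step momentum change equals the imposed body-force impulse to
$10^{-8}$ relative — membrane forces sum to zero and spreading preserves
totals exactly.

## The migration experiment

The full-scale study (50 µm vessel, millions of steps) is not a desk-scale
computation, so `run_vessel_migration()` reproduces migration *trends* in
a reduced vessel and asserts ordering, not absolute distances:

* straight (or sinusoidally curved) vessel, grid 48×24×24, diameter 22,
  $\tau = 1$, Re = 5 (body force from $a = 32\nu^2\mathrm{Re}/D^3$);
* one biconcave RBC (radius 4, 480 faces) with wall-shear capillary
  number 0.05 and $\kappa_\alpha/\kappa_s = 0.5$;
* one spherical DC (radius 2, 120 faces) with wall-shear capillary number
  0.01 — effectively rigid, its Taylor deformation stays below 1%;
* seeded random placement with wall clearance and pairwise separation;
  a short-range centroid repulsion (strength 0.05–0.2, gap 1.5) guards
  against numerical overlap — interactions are otherwise purely
  fluid-mediated;
* 32 000 steps (~0.9 ms at the reduced scale), recording the centreline
  distance $d(t)$, the normalised Taylor parameter, nodal force maxima and
  the interpolated pressure $c_s^2\rho$ at each centroid.

Both species migrate to near-wall annuli and plateau; the small stiff
carrier equilibrates farther from the axis than the larger, softer cell
(plateaus ≈ 6.2 vs ≈ 4.3 lattice units with the default seed), and it
equilibrates markedly faster. These orderings — not the plateau values —
are the asserted, scale-meaningful results; the absolute distances depend
on the reduced geometry.

**Stiff membranes and the sub-iteration scheme.** Explicit IB coupling is
unstable once a lattice-unit modulus exceeds roughly 0.1 (earlier for
finer Lagrangian meshes), while genuinely stiff carriers (shear moduli up
to 1 N/m, eight orders above an RBC) sit far beyond that. For such
particles `simulation(substeps = M, mobility = mu)` performs $M$
force sub-iterations per fluid step: the nodes relax internally
(overdamped, displacement `mu` × force per sub-iteration) and the fluid
receives the sub-iteration-averaged force. The transmitted stiffness is
effectively capped near $1/(M\mu)$ while the internal relaxation keeps the
shape on its constraint manifold, so the particle behaves as a
shape-preserving quasi-rigid body — the correct physical limit — at the
price of numerical membrane dissipation. The migration defaults are
$M = 40$, $\mu = 0.5$ for the RBC and $M = 20$, $\mu = 0.5$ for the DC.
The sheared-capsule validation uses plain explicit coupling
($M = 1$); its moduli are far below the ceiling.

A related numerical fact worth knowing: the Skalak law's restoring force
vanishes as a face collapses ($\partial W/\partial\lambda_2 \to 0$ as
$\lambda_2 \to 0$), so a strongly deformed tank-treading membrane can
crumple into slivers at mesh scale. Moderate capillary numbers, the
quadratic bending form, and the sub-iteration scheme together keep the
reduced-scale runs away from that path; the per-face stretch diagnostics
in `skalak_energy()` make it observable.

## What the reduced runs do and do not show

The synthetic configurations reproduce: laminar pipe hydrodynamics to
analytic accuracy; capsule deformation mechanics against first-order
theory; inertial/deformability migration to stable annuli; the
size/stiffness ordering of equilibrium positions; near-rigid carrier
behaviour (deformation < 2%). They do not reproduce: physiological
hematocrit (single particles only), absolute equilibration times or
distances of the full-scale vessel, non-Newtonian rheology, pulsatility,
adhesion chemistry, or Brownian effects — all outside the model. Passing
tests therefore validate the numerical machinery and the trend-level
physics, not quantitative in-vivo predictions.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| Divergence guard | abort at max lattice speed 0.3 or $\rho \le 0$ | compressibility error grows as $u^2$; 0.3 is far past trustworthy |
| Taylor estimator | gyration tensor | exact for affine shapes, noise-robust |
| Steady detector (shear) | $\Delta D < 0.1\%$ per 1000 steps | shear time $1/\dot\gamma$ spans many checks at the chosen units |
| Equilibration detector | trailing 20% window within 2% of $D/2$ | scale-free, permutation-stable to sub-tolerance noise |
| Repulsion guard | off by default; strength 0.2, gap 1.5 in migration | interactions are fluid-mediated in the model; guard is numerical |
| Poiseuille steps | 20 diffusion times $ (R/j_{0,1})^2/\nu$ | slowest pipe mode decays $e^{-20}$ |
| Wall model | staircase + halfway bounce-back | $D \ge 20$ resolves the lumen; no curved-boundary scheme in the model |

## Known limitations

* BGK (single relaxation time) couples the effective wall location weakly
  to $\tau$; the validation geometries pin the wall mid-link by
  construction, general geometries carry an $O(\Delta x)$ staircase error
  (observed first-order convergence of the pipe profile).
* The 2-point kernel trades smoothness for compactness: interfaces carry
  a half-lattice effective thickness, and very small capsules (radius
  ≲ 2) leak volume slowly — the global volume constraint compensates.
* Explicit coupling limits lattice-unit moduli; the sub-iteration scheme
  extends the range at the cost of extra dissipation, and is the wrong
  tool for strongly deformable membranes (use it only in the near-rigid
  regime).
* Single-precision-scale agreement with the printed lattice parameter
  table should not be expected row by row; two of its rows are internally
  inconsistent and the physical column is authoritative throughout.
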