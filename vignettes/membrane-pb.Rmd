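---
title: "Membrane-channel Poisson-Boltzmann electrostatics on tetrahedral finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-channel Poisson-Boltzmann electrostatics on tetrahedral finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pbmem)
```

# The model

`pbmem` solves the Poisson–Boltzmann (PB) equation for a fixed-charge
solute in an implicit solvent, extended with an implicit membrane: a slab
`z1 <= z <= z2` of low dielectric `eps_mem` spanning the box laterally.
In the dimensionless potential `u = e_c * beta * phi` the equation reads

```
-div(eps grad u) - s_c * sum_i z_i c_i exp(-z_i u) * 1_solvent
    = 4 pi k_e beta * sum_j q_j delta(r - r_j)
```

with `eps` piecewise constant per region (`eps_m` solute, `eps_s`
solvent, `eps_mem` membrane), ion species `(z_i, c_i)` present **only in
the solvent region** — not in the slab and not in the solute, but in the
recognised pore, which is solvent. Units are Angstrom / elementary charge
/ kcal/mol, with `k_e = 332.0637 A kcal/mol` and
`s_c = 4 pi k_e beta N_A 1e-27`. The default temperature is 298.15 K.
With these constants the analytic Born energy of a unit charge in a unit
sphere (2 inside, 80 outside) evaluates to -80.94 kcal/mol, and a 0.05 M
1:1 salt gives a Debye length of 13.7 A — two quick unit sanity checks
(`born_analytic()`, `debye_kappa()`).

The electrostatic solvation energy is the difference of two solves **on
the identical mesh** — solvated versus reference (uniform `eps_m`, no
ions): `dG_ele = 1/2 sum q_i (phi_sys,i - phi_ref,i)` with per-atom
potentials interpolated by the same P1 rule in both states. Same-mesh
cancellation matters: near a point charge the discrete potential carries
a mesh-dependent singular error which is identical in both states (the
local dielectric is `eps_m` in both) and cancels in the difference. The
solver refuses to combine solutions from different meshes.

Assumptions worth stating: sharp dielectric boundaries (no smoothing),
Boltzmann point ions (no finite-ion-size or Stern layer), a flat static
slab, and a rigid solute.

# Boundary conditions

Top and bottom box faces always carry Dirichlet data: a screened-Coulomb
superposition `u(r) = beta * sum_i k_e q_i exp(-kappa d_i)/(eps d_i)`.
The exterior dielectric follows the state: `eps_s` with the Debye `kappa`
for the solvated state, `eps_m` with no screening for the reference state
(whose true far field decays with the uniform solute dielectric; using
`eps_s` there would inject a spurious constant offset into the energy —
about 0.5% on the Born model at a 200 A boundary).

Lateral periodicity is realised by DOF identification: every vertex on an
`X_MAX`/`Y_MAX` face is matched to its translated copy on the opposite
face (the generators guarantee translation-consistent face meshes) and
the pair shares one unknown; box-edge vertices chain to a single master.
Assembly stays element-local; slave rows/columns are folded onto masters
afterwards, which preserves symmetry. Where a periodic face meets the top
or bottom face, Dirichlet wins — the z faces are prescribed
unconditionally, and in periodic mode the Dirichlet data use
minimum-image x/y distances, which makes the whole problem exactly
covariant under lattice translations of the molecule (verified to 1e-15
in the tests, including configurations wrapped across the seam).

The decomposition solver (`solve_decomposed`) splits the potential in the
solute into the analytic Coulomb part G, a discrete-harmonic part H with
`H = -G` on the solute boundary, and a regular remainder solved on the
whole domain. Its interface source is computed as the *variationally
consistent* discrete flux — the solute-restricted stiffness applied to
the nodal `G + H`, read off at interface rows — rather than by pointwise
quadrature of `d(G+H)/dn`, whose O(h) elementwise normal derivatives do
not converge in the surface integral (we observed a resolution-independent
~0.4% energy bias with the pointwise variant; the consistent flux removes
it). The energy `1/2 sum q_i (H_i + phi_r,i)` needs no reference solve.
Periodic decomposition is refused: a net solute charge has no periodic
solution without a neutralising background, which is out of scope.

# Singular charge treatments

Four treatments of the delta sources are provided. `direct` evaluates the
weak form exactly: each charge adds `q * lambda_k` to its containing
tet's vertices (barycentric coordinates, computed as sub-tet volume
ratios). The three assignment schemes build a continuous P1 density
instead: `vertex` places `4 q / |T_j|` on a charge-coincident vertex
(`|T_j|` = total volume of elements containing vertex j), `average`
spreads equally over all vertices within `r_cut` (default 1 A, the order
of the local edge length at production resolution), `weighted` uses
barycentric weights on the containing tet. Every scheme rescales
per-charge so the FE integral of its density equals the charge exactly
("integral invariance"); contributions of overlapping supports
superpose. Point location uses a nearest-vertex ring search with an
exhaustive bounding-box fallback; ties on shared faces resolve to the
lowest tet index, so results are deterministic.

On the Born fixture the average scheme is clearly the least accurate and
improves on refinement like the others; `weighted` degenerates exactly to
`vertex` when the charge sits on a vertex, and is then numerically
indistinguishable from `direct` in the energy.

# Membrane insertion and pore recognition

`label_membrane` relabels solvent elements whose centroid falls in the
slab — deliberately including the water-filled channel, since geometry
alone cannot distinguish it. `detect_pore` then recovers the channel: a
flood fill over shared-face adjacency among non-solute elements inside
the slab, started from a seed (`"auto"`: the solute bounding-box axis
midpoint snapped to the nearest non-solute element). Face adjacency (not
vertex adjacency) prevents leakage through single shared vertices, and
being direction-free it handles tilted channels with no special cases.
Two rejection rules classify failures: a component that reaches the box
sides is bulk membrane, not a channel ("not laterally enclosed"); one
that fails to touch solvent beyond *both* slab faces is a dead-end cavity.
Element membership is decided by centroid, matching the slab-labelling
rule, so slab insertion and pore restoration are exact inverses on pore
elements; the recognised set agrees with the analytic cylinder of the toy
fixture up to elements within one local edge of the wall.
`fill_pore_partial` implements the control experiment that re-fills a
central band of the pore of height `hmp` with membrane, quantifying the
cost of failing to recognise the channel.

# Discretisation and solvers

P1 (linear tetrahedral) elements throughout. The stiffness matrix is
assembled from closed-form barycentric gradients, vectorised over
elements; rows sum to zero before boundary conditions and the matrix is
symmetric in all modes (checked in tests). The nonlinear ionic term is
integrated with the 4-point degree-2 tetrahedral rule, interpolating `u`
to quadrature points and exponentiating there (exponents are soft-clamped
at 40 to guard intermediate iterates; converged solutions sit far below
the clamp). The Jacobian `A + M_ion(u)` is symmetric positive definite,
so each damped-Newton step is an SPD solve: initial damping 0.5, doubled
towards 1 on residual decrease, halved on increase (backtracking),
convergence at a 1e-9 relative residual. With no ions the equation is
linear and solved directly; a linearised (Debye–Hückel) operator is
available as the small-charge oracle, and the nonlinear solution matches
it to first order with an O(q^3) remainder (the factor-8 halving test).

Linear systems up to 60k unknowns use CHOLMOD's supernodal Cholesky
(`Matrix`); larger ones switch to Jacobi-preconditioned conjugate
gradients at a 1e-10 relative residual (about 400 iterations on the
largest graded Born systems used here, ~230k DOFs). The crossover keeps
peak memory modest on strongly graded meshes, where direct factors fill
badly.

# Synthetic fixtures: what they emulate, and what they do not

`make_born_mesh` builds layered icosphere shells: the dielectric
interface and the outer boundary are mesh surfaces, the centre is a
vertex (so vertex-on-charge works), and solvent shells are geometrically
graded out to 200 A. The default (subdivision 2, 21 solvent shells,
~21k elements / ~3.7k DOFs) matches the coarse single-ion study scale.
Faceting matters: a subdivision-2 icosphere underestimates ball volumes
by ~3%, so volume checks carry that tolerance.

`refine_uniform` is edge-midpoint octasection (children inherit region
labels; boundary markers propagate; the interior octahedron is split
along its shortest diagonal). By default midpoints stay put, which
conserves region volumes exactly but freezes the faceted interface at its
coarse shape — precisely what happens when a body-fitted mesh whose
surface was triangulated once is refined uniformly. With
`project = radial_projection()` new vertices are instead placed at the
mean parent radius, so every shell converges to its sphere and the
geometric error vanishes with h. The two options separate two error
mechanisms cleanly, and the Born refinement studies exploit that: under
plain refinement the singular-charge error decreases and then *increases*
(the computed energy converges to the faceted polyhedron's value, past
the true sphere's), reproducing the classic non-monotone behaviour of
refining around point charges with a fixed molecular surface; under
projected refinement the regular uniform-ball charge model converges
monotonically, as a smooth source should. The uniform-ball model has the
same closed-form energy as the point charge (the reaction potential is
constant inside the ball), which is what makes it the clean regular
counterpart.

`make_box_mesh` splits every cube of a structured grid with the same Kuhn
6-tet pattern, so interior faces match and opposite box faces are exact
translated copies — the property the periodic stitching requires.
`make_channel_system` carves an annular solute plug around a cylindrical
(optionally tilted) pore, with a ring of point charges mid-wall, and
`label_solute` builds staircase cavities around atom spheres (minimum
image in x/y for periodic covariance). These dielectric boundaries are
staircase, not body-fitted: good for trend and invariance experiments,
not for publication-quality absolute energies of real proteins — real
use consumes body-fitted TetGen meshes via `read_tetgen`. For the
box-size comparison study the cavity margin defaults to 6 A, comfortably
above the 4.3 A tet diameter of the h = 2.5 A meshes, so that atoms sit
well inside the cavity and the direct and decomposition routes are both
well resolved; with the cavity under-resolved their agreement degrades
before either answer is trustworthy.

Problem sizes in the test-suite experiments are chosen for single-CPU
desk scale: Born studies up to ~230k DOFs (three levels) or ~254k (four
levels on the coarser variant), box sweeps at h = 2.5 A up to a 100 A
box (~69k DOFs), channel experiments at ~7k DOFs. The full suite runs in
a few minutes.

# Defaults and tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| `eps_m`, `eps_s`, `eps_mem` | 2, 80, 2 | – | standard solute/water values; slab varied 1–8 in sweeps |
| temperature | 298.15 | K | reproduces the quoted Born constant set |
| membrane slab | z = −15 … 15 | A | typical bilayer half-thickness, the sweep default |
| ionic strengths (sweeps) | 0, 0.05, 0.25, 0.5 | mol/L | the standard study grid |
| SASA probe / points | 1.4 / 960 | A / – | water probe; Fibonacci sampling error ≈ area/960 |
| tension profile | gamma 0.005, s_core 0, ramp 3 | kcal/mol/A², –, A | hydrophobic slab core; all three exposed in `surface_tension_profile` |
| `r_cut` (average scheme) | 1.0 | A | order of the local edge at production resolution |
| Newton | tol 1e-9, relax 0.5, max 50 | – | converges in ≤ 10 iterations on all fixtures |
| linear solves | Cholesky ≤ 60k DOFs, else Jacobi-PCG 1e-10 | – | memory/speed crossover |
| production resolution | ~0.36–0.37 | A (equiv. edge) | the error minimum of the refinement study; ≈ 0.25 A cubic grid |

# Known limitations

No size-modified or nonlocal PB, no Stern layer, no multigrid, no
adaptive refinement, single through-channel only (the first through
component), flat membranes only, and no periodic decomposition solve.
The tilt scan minimises the total energy over rigid rotations only — no
internal degrees of freedom. Fixture meshes use staircase dielectric
boundaries; conclusions drawn from them are about trends and
invariances, not absolute energies of real structures.
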