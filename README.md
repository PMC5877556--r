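# pbmem

Finite-element Poisson–Boltzmann electrostatics for membrane channel
systems, in R.

Membrane channel proteins sit in a lipid bilayer and conduct ions through
a water-filled pore. Estimating their solvation free energy with an
implicit-solvent Poisson–Boltzmann (PB) model needs three ingredients that
plain PB solvers lack: a low-dielectric membrane slab, recognition of the
channel region (which must keep the solvent dielectric and remain
ion-accessible, even when the channel is tilted), and lateral periodic
boundary conditions so the box tiles an infinite membrane plane instead of
imposing an artificial boundary next to the protein. `pbmem` implements
all three on linear tetrahedral finite elements, for people who want a
scriptable, fully inspectable PB pipeline at desk scale: method developers,
teachers, and anyone validating membrane-PB results produced by larger
codes.

## The model

The dimensionless potential u = e_c βφ solves

    -div( eps(r) grad u ) - s_c Σ_i z_i c_i exp(-z_i u) · 1_solvent(r)
        = 4π k_e β Σ_j q_j δ(r - r_j)

with eps = eps_m in the solute, eps_s in the solvent (including the pore)
and eps_mem in the slab z1 ≤ z ≤ z2; mobile ions (bulk molarities c_i,
valences z_i) exist only in the solvent region. Dirichlet values from a
screened-Coulomb superposition are imposed on the top and bottom box
faces; the x/y faces are either Dirichlet or periodically identified
("stitched") so that opposite-face vertices share one unknown. The
electrostatic solvation energy is

    ΔG_ele = ½ Σ_i q_i (φ_i,sys − φ_i,ref)

from two solves on the *identical* mesh: the solvated state and a
reference state with uniform eps_m and no ions. The total adds a
non-polar term ΔG_np = γ Σ_i S(z_i)·SA_i with Shrake–Rupley per-atom
accessible areas and a membrane-depth-dependent tension profile S(z).

The singular right-hand side can be treated four ways (`charge_method`):
direct delta integration of the weak form, vertex-on-charge, equal
(average) assignment in a truncation sphere, and barycentric-weighted
assignment — all assignment schemes conserve the total charge to 1e-12 by
construction. A singular/harmonic/regular decomposition solver
(`solve_decomposed`) provides an independent route for cross-validation.

Everything is generated in code: concentric-sphere Born meshes
(`make_born_mesh`), periodic-ready structured boxes (`make_box_mesh`),
toy channel systems with an annular protein plug around a straight or
tilted cylindrical pore (`make_channel_system`), and seeded random charge
clusters (`make_random_cluster`). TetGen-style `.node/.ele/.face`, PQR
and legacy VTK files are read/written for interoperability.

## Worked example 1: the Born ion

A unit charge at the centre of a 1 Å sphere (eps_m = 2) in a 200 Å
solvent sphere (eps_s = 80) has the analytic solvation energy
`born_analytic()` = −80.94 kcal/mol. The refinement study solves the FEM
problem on the graded fixture mesh and one uniform refinement:

```r
library(pbmem)
born_study(levels = 2)
#>   level elements  dofs edge_equiv    dG_ele error_pct
#> 1     0    21440  3727  0.8259180 -79.55833 1.7076722
#> 2     1   171520 29053  0.4185922 -80.57626 0.4500428
```

At the refined level the equivalent edge length near the ion is ~0.42 Å
and the energy is within 0.45% of the closed form. The `error_pct` column
is `|ΔG_exact − ΔG_h| / |ΔG_exact| × 100`.

## Worked example 2: a toy membrane channel

```r
sys   <- make_channel_system(channel_spec())      # plug + pore + ring charges
mspec <- membrane_spec(z1 = -15, z2 = 15, eps_mem = 2)
mesh  <- label_membrane(sys$mesh, mspec)          # slab (fills the pore too)
pore  <- detect_pore(mesh, mspec, seed = "auto")  # flood-fill recognition
mesh  <- apply_pore(mesh, pore)                   # pore back to solvent
#> length(pore) is 984 elements

params <- physics_params(eps_mem = 2, species = salt_species(0.05))
ele  <- electrostatic_solvation(mesh, sys$mol, params, bc_mode = "periodic")
prof <- surface_tension_profile(z1 = -15, z2 = 15)
np   <- nonpolar_energy(sys$mol, compute_sasa(sys$mol), prof)
energy_report(ele$dG_ele, np)
#> dG_ele = -211.05, dG_np = 0.00, dG_sol = -211.05 kcal/mol
```

The −4 e charge ring sits at the slab midplane where the tension profile
S(z) is zero, so the non-polar term vanishes here; tilting the system
(`tilt_scan`) exposes buried area and makes it positive. Sweep drivers
(`membrane_sweep`, `thickness_sweep`, `hmp_study`, `box_sweep`) reproduce
the standard membrane-PB experiments on these fixtures; a thin CLI
(`exec/pbmem`) exposes the same verbs from a shell.

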