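---
title: "Methods: DMRG/FQ polarizable embedding in dmrgfq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMRG/FQ polarizable embedding in dmrgfq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `dmrgfq`, the numerical
choices behind them, and what the package's tests do and do not establish.

## The coupled model

The total energy of a solvated chromophore is split into three pieces,

$$E = E_\mathrm{DMRG} + E_\mathrm{FQ} + E_\mathrm{int},$$

a quantum active-space energy, a classical fluctuating-charge energy, and
their electrostatic coupling. All internal quantities are in Hartree atomic
units; XYZ input is Angstrom and converted on read
(1 Å = 1.8897261254578281 Bohr).

### Active-space wave functions as matrix product states

The solute is described by a complete-active-space (CAS) wave function over
$L$ active orbitals with the second-quantized Hamiltonian
$\hat H = \sum_{pq} h_{pq} \hat E_{pq} + \tfrac12 \sum_{pqrs} g_{pqrs}
(\hat E_{pq}\hat E_{rs} - \delta_{rq}\hat E_{ps})$, $g$ stored in chemist
notation $(pq|rs)$ with its 8-fold permutational symmetry enforced on
input. The CI tensor is factorized into an MPS with physical dimension 4
per orbital (local basis $|0\rangle, |\!\uparrow\rangle, |\!\downarrow
\rangle, |\!\uparrow\downarrow\rangle$) and bond dimension capped at $M$.

The Hamiltonian MPO is assembled symbolically: every spin-orbital operator
string (with Jordan–Wigner parities along the orbital chain) is a rank-1
MPO; strings are summed in batches of 64 and the running sum recompressed
by QR/SVD sweeps with a relative singular-value cutoff of $10^{-14}$. This
is exact to numerical precision — the test suite checks the densified MPO
against an independently constructed Fock-space Hamiltonian at $10^{-12}$ —
and yields operator bond dimensions polynomial in $L$.

Ground states are optimized with the standard two-site sweep: each local
two-site problem is solved by a Davidson iteration (diagonal
preconditioner, deterministic start from the current tensor, tolerance
tightening from $10^{-6}$ to $10^{-10}$ over the sweeps; problems of
dimension $\le 256$ are solved densely), and the optimized pair tensor is
split by SVD keeping $\min(M, \#\{\sigma_i > 10^{-14}\sigma_1\})$ singular
values, truncating deterministically by index when a degenerate shell
straddles the cut. The per-sweep energy reported is the variational
expectation $\langle\psi|\hat H|\psi\rangle$ of the truncated, normalized
state; if a sweep raises it (possible near the fixed point at strongly
truncated $M$, where truncation loss can exceed the local gain), the
previous sweep's state is kept and the sweep loop stops, so the reported
trace is monotone non-increasing. Non-convergence within the sweep budget
returns the best state with a warning, never silently.

### Quantum-number and spin targeting

Rather than block-sparse symmetry labels on the bonds, the package targets
a $(N, 2S_z)$ sector with dense tensors plus a commuting penalty MPO
$w[(\hat N - N)^2 + (\hat S_z - S_z)^2]$ (default $w = 10$ Hartree) and,
for $S_z = 0$, a total-spin penalty $w_S \hat S^2$ (default 5 Hartree) that
leaves singlets exactly unchanged while lifting higher-spin states by at
least $2 w_S$. Because both penalties commute with any particle- and
spin-conserving Hamiltonian, in-sector eigenvalues are bitwise those of the
bare Hamiltonian; the tests confirm that the penalized and penalty-free
paths produce identical energies when the global ground state already lies
in the target sector. At truncated $M$ the optimized state carries a small
off-sector admixture and the penalty contributes a correspondingly small
positive bias; at the bond dimensions used for production quantities
($M = 4^{\lfloor L/2\rfloor}$ on the fixtures) the representation is exact
and the bias vanishes.

### Excited states

The first excited singlet is obtained state-specifically: the ground state
is converged first in the same orbital basis, then a second MPS is
optimized with the ground state projected out of every local Davidson
space (overlap environments are tracked alongside the Hamiltonian
boundaries). The excited-state guess is a deterministic mixture of the
sector determinant least overlapping the ground state with a damped copy
of the ground state itself. The projection choice (rather than
state-averaging) is recorded in run metadata through the state label; the
test suite checks $|\langle\Psi_\mathrm{ES}|\Psi_\mathrm{GS}\rangle| \le
10^{-6}$ at convergence.

### Reduced density matrices

$D_{pq} = \langle \hat E_{pq}\rangle$ and $P_{pqrs} = \langle \hat E_{pq}
\hat E_{rs} - \delta_{rq}\hat E_{ps}\rangle$ are evaluated as
Jordan–Wigner string expectations over the left-canonicalized MPS with
cached right environments, using the hermiticity $P_{pqrs} = P_{srqp}$ to
halve the work. In this chemist index convention the partial trace obeys
$\sum_r P_{pqrr} = (N-1) D_{pq}$, which the tests assert together with
term-by-term agreement with brute-force operator expectations and exact
energy reconstruction $E = \sum h D + \tfrac12 \sum g P + E_\mathrm{core}$.

### Fluctuating charges

Each classical atom carries an electronegativity $\chi$ and hardness
$\eta > 0$ (Hartree-based units, loaded from YAML parameter files keyed by
element; published parameter sets are configuration inputs, not shipped
constants). The interaction kernel is the Ohno form
$T_{ij} = \bar\eta_{ij}/\sqrt{1 + \bar\eta_{ij}^2 r_{ij}^2}$ with
$\bar\eta_{ij}$ the arithmetic mean of the hardnesses, applied to **all**
pairs, intra- and inter-molecular alike; it reaches the Coulomb $1/r$ limit
from below (relative deviation $1/(2\bar\eta^2 r^2)$, under 1% once
$\bar\eta r > 10$) and saturates at $\bar\eta$ as $r \to 0$, which is what
prevents the polarization catastrophe. Charges solve the bordered symmetric
system
$$\begin{pmatrix} T & \mathbf 1_\lambda \\ \mathbf 1_\lambda^T & 0
\end{pmatrix}\begin{pmatrix} q \\ \lambda\end{pmatrix} =
\begin{pmatrix} -\chi - V \\ Q\end{pmatrix}$$
by direct dense factorization — system sizes are at most thousands, so no
iterative solver is warranted — with one Lagrange multiplier per molecule
pinning its total charge (no intermolecular charge transfer). Singular
systems (e.g. duplicated atoms) fail with the offending rows named.

### Electrostatic coupling

The QM potential at charge site $s$ is $V_s(D) = \sum_N Z_N/|r_s - R_N| -
\mathrm{Tr}(D\,V^s)$ with $V^s_{pq} = \langle\phi_p|1/|r - r_s||\phi_q
\rangle$ stored positive as written; the minus sign lives only in the two
assembly routines (integral folding and interaction energy) to prevent
double negation. $D$ is the total one-particle density: the doubly occupied
core contributes a scalar per site folded into the core energy, the active
block enters the effective one-electron integrals $h^\mathrm{eff}_{pq} =
h_{pq} - \sum_s q_s V^s_{pq}$. This makes the identity
$\langle\hat H^\mathrm{eff}\rangle + E^\mathrm{eff}_\mathrm{core} -
\langle\hat H\rangle - E_\mathrm{core} = \sum_s q_s V_s(D)$ exact, which
the tests verify at $10^{-10}$.

### Orbital optimization

The orbital gradient over non-redundant rotation pairs (inactive–active,
inactive–virtual, active–virtual) is $2(F^T - F)$ with $F$ the generalized
Fock matrix built from the full-space densities (core blocks composed
analytically from the active $D$, $P$). Charges enter exactly through the
folded one-electron integrals, so the same expression yields the
FQ-augmented gradient. Orbitals are updated as $C\exp(\kappa)$ with
$\kappa$ antisymmetric: each macro-iteration minimizes the fixed-density
energy in $\kappa$ by BFGS, caps the step at $\lVert\kappa\rVert \le 0.4$
(trust region) with halving backtracks so the fixed-density energy strictly
decreases, and re-orthonormalizes symmetrically against the AO overlap.
Because the fixed-density energy upper-bounds the re-optimized total
energy, macro-iteration energies are monotone non-increasing. A quasi-Newton
step satisfies the same Brillouin stationarity condition as a super-CI
solver; the contract checked by the tests is the condition itself (gradient
norm below tolerance, finite-difference agreement at $10^{-6}$, energy
agreement with an independently optimized CI reference at $10^{-8}$).
Active–active rotations are treated as redundant, standard CAS practice; at
truncated $M$ they are only approximately redundant, an accepted
approximation checked numerically on the fixtures.

### The coupled macro-iteration

A state-specific run performs: starting orbitals (restricted Hartree–Fock
from the built-in backend, or supplied — excited-state runs are seeded with
the converged ground-state orbitals); an unpolarized MPS solve for the
initial density; an initial polarized charge solve with $V(D)$ as source;
then repeats (a) MPS re-optimization under the charge-folded effective
Hamiltonian, (b) orbital update with FQ terms in the gradient, (c) charge
update from the polarized solve — the loop order follows the protocol the
method prescribes — until $|\Delta E| < 10^{-8}$ Hartree **and**
$\max|\Delta q| < 10^{-6}$ (both configurable). Charge mixing
$q \leftarrow \alpha q_\mathrm{new} + (1-\alpha) q_\mathrm{old}$ is off by
default ($\alpha = 1$) and engages at $\alpha = 0.5$ if the energy trace
rises. Embedding modes: `polarizable` (full mutual polarization), `frozen`
(fixed charges folded once), `none` (gas phase). A bond-dimension ladder
(warm-up at small $M$, production at larger $M$, seeding each stage from
the previous state) is available through repeated calls with `guess`;
excited-state charges initialize from the ground-state solve.

At convergence the Lagrangian functional $E(D, P, q, \lambda)$ is
stationary in every single-charge direction — the acceptance checks perturb
each charge by $\pm 10^{-4}$ and find first-order residuals below
$10^{-7}$ — and displacing the environment to $10^4$ Bohr recovers the
gas-phase energy to $10^{-8}$ with the isolated-molecule charges.

### Orbital ordering

Active orbitals can be ordered by the Fiedler vector of the graph
Laplacian built from exchange-coupling weights $w_{pq} = |(pq|qp)|$ — the
weight choice is a package decision (the exchange magnitude is the common
choice where the coupling measure is not otherwise specified) and is
recorded in the permutation returned to the caller. Ties break by ascending
orbital index, the global direction is fixed so the first retained index
precedes the last, and disconnected components are ordered independently
with a warning.

## The synthetic-data generator

`generate_fixtures()` emits the package's study conditions:

* `fcidump_random` — symmetric $h$ with dominant diagonal
  ($h_{pp} \in [-2, -1]$), 8-fold-symmetric $g$ with two-electron scale 0.4
  (strong correlation relative to the one-electron spacing, so truncated-$M$
  behavior is actually exercised), positive $(pp|pp)$;
* `fcidump_h2like` — a two-orbital, two-electron Hamiltonian with a known
  singlet spectrum;
* `toy_snapshots` — a rigid H$_2$ solute plus diatomic solvent molecules
  placed along distinct directions at 3 Å spacing (first-solvation-shell
  contact distance) with 0.3 Å Gaussian positional jitter (thermal
  displacement scale), or at programmed distances for droplet tests;
* `fq_params` — synthetic per-element $(\chi, \eta)$ sets with $\eta$
  around 0.5–0.7 Hartree, the magnitude typical of published FQ
  parameterizations.

Same seed, byte-identical files; every fixture round-trips through its
reader. These toys emulate the *structure* of real solvated-chromophore
studies (frames, droplets, grouping, mutual polarization) but not their
physics: a minimal-basis H$_2$ has no low-lying valence excitation, tiny
polarizability and no hydrogen-bonding anisotropy, so passing tests
demonstrate correctness of the machinery — oracle equivalence,
variational ordering, stationarity, conservation laws — not chemical
accuracy for real solutes. Production-scale studies (large actives spaces,
diffuse bases, hundreds of MD frames) are outside the scope of the shipped
backend; externally produced FCIDUMP Hamiltonians are the supported route
to heavier solutes in gas phase.

## Numerical choices and degenerate inputs

* Bordered FQ solves use `solve()` on the dense symmetric system; rank
  deficiency is reported with the offending rows.
* QR decompositions un-pivot the column permutation and fall back to an
  SVD if the LAPACK factors are non-finite (observed for exactly
  rank-deficient MPO matricizations).
* Coincident FQ atoms are rejected as singular geometry; FQ sites within
  $10^{-6}$ Bohr of a nucleus are rejected in the nuclear-potential term.
* Odd electron counts with $2S_z = 0$ are an empty sector and rejected at
  MPS initialization.
* Checkpoints (MPS tensors, gauge, metadata; coupling states) are RDS
  containers behind `save_mps()`/`load_mps()` and
  `save_coupling_state()`/`load_coupling_state()`.

## Problem sizes used in the shipped validation

The test and acceptance workloads run full oracle cross-checks at $L \le
6$ active orbitals (exact diagonalization stays cheap there), with 20
random Hamiltonians for the DMRG/exact-diagonalization equivalence, 50
random FQ systems of up to 30 atoms and 5 molecules against a constrained
minimizer, 4-orbital CAS(2,2) fixtures for gradient and CASSCF
equivalence, a 9-atom 3-water FQ environment for coupling diagnostics, and
a 5-frame toy ensemble end to end. These sizes were chosen so each oracle
is unambiguous and the whole suite stays interactive.

## Known limitations

* The built-in integral backend is s-type only and its bases are synthetic;
  it exists to exercise the full coupled machinery on models, not to
  approach basis-set completeness. Any external backend producing overlap,
  core Hamiltonian, ERI and point-potential matrices fits the same
  interface; FCIDUMP import bypasses the backend (gas phase only, since ESP
  operators are then unavailable).
* One-site DMRG, spin-adapted (SU(2)) tensors, dynamic-correlation
  corrections, nonelectrostatic (Pauli/dispersion) solute–solvent terms,
  oscillator strengths and nuclear gradients are not implemented.
* Charge transfer between FQ molecules is excluded by construction (one
  constraint per molecule).
* The excited-state solver targets the first excited singlet; higher roots
  would need additional projections.
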