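---
title: "Adaptive ansatz growth for molecular ground states: model, conventions, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive ansatz growth for molecular ground states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptvqe)
```

## The problem and the method

The electronic ground state of a molecule in a finite orbital basis is the
lowest eigenvector of the second-quantized Hamiltonian

$$\hat H = E_\mathrm{core} + \sum_{pq,\sigma} h_{pq}\,
a^\dagger_{p\sigma} a_{q\sigma} + \tfrac12 \sum_{pqrs,\sigma\sigma'}
(pq|rs)\, a^\dagger_{p\sigma} a^\dagger_{r\sigma'} a_{s\sigma'}
a_{q\sigma},$$

with $h_{pq}$ and $(pq|rs)$ the one- and two-electron integrals over
molecular orbitals (chemists' notation, Hartree units).  A variational
quantum eigensolver (VQE) minimizes $\langle\psi(\vec\theta)|\hat
H|\psi(\vec\theta)\rangle$ over a parameterized state.  The fixed ansatz of
unitary coupled cluster with singles and doubles (UCCSD),
$e^{\hat T - \hat T^\dagger}|\psi_\mathrm{HF}\rangle$, is accurate for
weakly correlated molecules but carries every excitation parameter whether
the molecule needs it or not, and degrades for strong correlation.

The adaptive alternative implemented here grows the ansatz one operator at
a time.  A fixed *pool* of anti-Hermitian excitation generators
$\{\hat A_k\}$ is prepared once.  Each iteration:

1. prepares the current trial state $|\psi\rangle$;
2. measures $g_k = \langle\psi|[\hat H, \hat A_k]|\psi\rangle$ for every
   pool member — the exact derivative of the energy with respect to a new
   parameter appended on the left at value zero;
3. stops if the gradient norm is below a threshold $\varepsilon$;
4. otherwise appends the operator with the largest $|g_k|$ (ties resolved
   to the lowest pool index) with a new parameter initialized at zero, and
   re-optimizes *all* parameters, warm-started from the previous optimum.

Selection never removes an operator from the pool, so an operator can
recur; products of recurring one- and two-body unitaries are exactly what
makes the factorized form complete in the limit.  The result, at threshold
$\varepsilon$, is

$$|\psi^{(\varepsilon)}\rangle = e^{\theta_N \hat A_{k_N}} \cdots
e^{\theta_1 \hat A_{k_1}} |\psi_\mathrm{HF}\rangle,$$

with as many parameters as iterations.  We emulate all of this classically
with exact statevectors: expectation values are deterministic, there is no
shot noise, and "measurement" is matrix algebra.

## Conventions that define the implementation

**Spin orbitals and qubits.** Spin orbital $2p$ is spatial orbital $p$
(0-based) with $\alpha$ spin, $2p+1$ the $\beta$ partner.  Under the
Jordan–Wigner mapping, qubit index = spin-orbital index and qubit 0 is the
least-significant bit of the computational-basis index.  Operator labels
printed by the package use the field's 1-based spatial notation with a `b`
suffix for $\beta$ (e.g. `tau_{2 2b}^{3 6b}`).

**Pool construction.** Generators are built from excitations
$t = a^\dagger_{vir}\cdots a_{occ}$ as $\tau = t - t^\dagger$ with
coefficients $\pm 1$ (no $\tfrac12$ or normalization factors: the
variational parameter absorbs scale), then summed with their *spin
complement* — the same excitation with all spins flipped.  Two conventions
here are load-bearing and were fixed by reproducing published results
rather than by aesthetics:

* *Complement sign.*  Flipping the spins of a double excitation whose
  occupied or virtual pair is the $\alpha\beta$ pair of one spatial
  orbital inverts that pair's canonical index order, so the complement
  re-enters with a fermionic sign $-1$.  Dropping this sign builds the
  anti-symmetric rather than symmetric combination and suppresses the
  gradients of exactly the "correlated single" operators
  ($\hat n_j a^\dagger_a a_i$-type) that dominate stretched-geometry
  ansätze; the selection sequence for LiH then fails to match the
  published 8-operator ansatz, while with the sign it matches operator
  for operator.

* *Convergence-norm multiplicity.*  The pool stores each distinct
  generator once.  In an enumeration over spatial index quadruples
  $\tau_{pq}^{rs}$, however, every double built from a same-spatial
  $\alpha\beta$ pair arises twice (its exchange partner equals it up to
  sign), so its gradient appears twice in the $L^2$ convergence norm.
  `adapt_config(norm_multiplicity = TRUE)` (the default) counts those
  squared gradients twice — selection is unaffected.  With a plain norm
  the loose-threshold ($\varepsilon = 0.1$) runs stop two to three
  operators early, exceeding chemical accuracy at stretched LiH
  geometries; with the multiplicity convention the full LiH dissociation
  scan reproduces the published behavior (at most 9 parameters, every
  point within 1 kcal/mol, mean errors on the published scale).

**Restricted vs generalized pools.** `build_sd_pool()` restricts
excitations to occupied→virtual moves from the Hartree–Fock reference;
`build_gsd_pool()` ranges over all spatial indices and deliberately
includes operators that annihilate the reference (occupied→occupied,
virtual→virtual) — they contribute only once the wavefunction is
entangled, which is why a lexically ordered generalized growth curve stays
flat at $E_\mathrm{HF}$ for its first steps.  Adaptive runs use the
generalized pool by default.

**UCCSD parameter accounting.** For LiH in a minimal basis (6 spatial
orbitals, 2 occupied) there are 92 raw $S_z$-conserving spin-orbital
amplitudes.  The published count of 64 "spin-complemented" parameters
corresponds to tying each mixed-spin double to its spin-flip partner while
keeping singles and same-spin doubles as separate per-spin parameters;
that is what `uccsd_parameter_count()` and the UCCSD baseline implement.
A *full* orbit merge — additionally tying the $\alpha/\beta$ singles pairs
and the $\alpha\alpha/\beta\beta$ doubles pairs, which is what the pool
construction uses, consistent with how published ansatz listings write
single spin-complemented operators — would give 50; both counts are
computed, not assumed:

```{r}
uccsd_parameter_count(6, 2)
pool_size(build_sd_pool(6, 2))
```

## Numerical machinery

**Sector compilation.** The Hamiltonian and every generator conserve
particle number and $S_z$, so `compile_system()` projects all matrices
onto the reference sector (e.g. $\binom{6}{2}^2 = 225$ of 4096 basis
states for LiH, $\binom{7}{3}^2 = 1225$ of 16384 for BeH$_2$).  This is an
exact reformulation, verified in the tests against full-space
diagonalization, and is what makes desk-scale scans fast.

**Exponential action.** $e^{\theta A}|\psi\rangle$ uses a scaled Taylor
series: the rotation splits into $\lceil|\theta|\,\|A\|_\infty\rceil$
segments, each summed to a relative tolerance of $10^{-13}$ (at most 60
terms).  Norm preservation to $10^{-10}$ is asserted property-style in the
tests rather than imposed by renormalization.

**Analytic gradient.** For the product ansatz, one forward sweep stores
the intermediate states and one backward sweep propagates $H|\psi\rangle$
through the adjoint rotations, giving all $\partial E/\partial\theta_k =
2\,\mathrm{Re}\langle\lambda_k|A_k|\psi_k\rangle$ for at most $3N + O(1)$
exponential applications versus $N$ for the energy alone — the classical
realization of obtaining the whole gradient at roughly twice the cost of
an energy evaluation.  An instrumented counter (`exp_count()`) enforces
the bound in the tests.

**Inner loop.** Limited-memory BFGS (`optim(method = "L-BFGS-B")`) with
the analytic gradient, projected-gradient tolerance $10^{-8}$
Hartree/radian — kept two orders below the tightest supported
$\varepsilon = 10^{-3}$ so optimizer noise cannot contaminate the pool
gradient-norm stopping test — and a best-seen guard so warm-started
re-optimizations are monotone.  The un-Trotterized UCCSD baseline
exponentiates the *summed* generator exactly; its gradient uses the
integral representation of the exponential's directional derivative,
discretized by Gauss–Legendre quadrature (the integrand is entire, so the
node count, at least 16 and growing with $\|T\|$, is conservative;
agreement with finite differences is tested to $10^{-7}$).

**Exact reference.** `fci_ground()` diagonalizes the sector-projected
Hamiltonian densely — every system treated here has sector dimension at or
below 1225, where dense symmetric eigensolvers are both faster and more
robust than iterative ones — and checks the residual
$\|Hv - Ev\| < 10^{-9}$.

**Thresholds from one run.** The loop is deterministic, so a run to
$\varepsilon_3 = 10^{-3}$ contains the $\varepsilon_1$ and $\varepsilon_2$
runs as prefixes; `adapt_at_threshold()` extracts them, and a test
verifies the extraction equals an actual run at the looser threshold.

## What the synthetic generators emulate

`toy_integrals("random_twobody")` draws a symmetric $h$ and an
8-fold-symmetric $g$ from a seeded normal distribution with a roughly
level-ordered diagonal: it emulates the *algebraic structure* of molecular
integrals (Hermiticity, permutational symmetry, a meaningful HF reference)
without any molecular physics, and is what the property-style tests
randomize over.  `toy_integrals("pairing")` is a seniority-zero pairing
model: evenly spaced levels with constant pair hopping, the minimal model
of pair correlation.  Passing tests on these fixtures demonstrates
algebraic correctness (gradients, symmetries, variational bounds) — not
chemical accuracy, which is assessed against the shipped STO-3G integrals
for H$_2$, LiH, BeH$_2$ and H$_6$ (see `inst/extdata/fcidump/README` for
their provenance and literature validation).

## Study conditions and problem sizes

The packaged dissociation grids follow the geometries of the reference
systems: LiH from 0.8 to 4.0 Å in steps of 0.2; linear BeH$_2$ at
1.2/1.8/2.39/3.0 Å; collinear H$_6$ with adjacent spacings
0.8/1.2/1.6/2.0 Å.  The published tables do not print their scan grids, so
mean-error comparisons are order-of-magnitude by construction; the
package's own summaries always record the grid used.  The BeH$_2$ and
H$_6$ sets are deliberately small, evenly spaced subsets of the full
curves — they cover equilibrium through strongly stretched geometries,
which is where the methods separate, while keeping a full test run at
desk scale.  H$_6$ at 2.0 Å is the strong-correlation stress case: the
restricted HF determinant is ~0.5 Hartree above FCI there, UCCSD misses
chemical accuracy, and tight-threshold adaptive runs need on the order of
a hundred operators.

## Degenerate inputs, ties, edge cases

Degenerate pool gradients (symmetry partners such as the two $\pi$
orbitals of LiH) are resolved to the lowest canonical pool index, making
runs platform-independent.  Excitations whose generator vanishes
identically (source equals destination) are dropped at pool construction.
An already-exact reference exits at iteration zero with an empty ansatz.
A false gradient trough — a plateau where the norm dips below a loose
threshold while correlation energy remains — is detected diagnostically
(`detect_false_trough()`) but never alters the algorithm, matching the
reference treatment of premature termination as a threshold artifact.

## Known limitations

* No shot-noise or density-matrix (hardware noise) emulation: expectation
  values are exact, so measurement-cost questions are out of scope.
* Jordan–Wigner only; the tree-parity (Bravyi–Kitaev) mapping is an
  interface stub.
* Closed-shell restricted references only; no frozen core, no point-group
  symmetry exploitation.
* Pools stop at two-body generators; multi-operator growth per iteration
  and Hessian-based cooperative selection are config-reserved but not
  implemented.
* The integral provider hook ships with FCIDUMP files only; there is no
  built-in integral engine.
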