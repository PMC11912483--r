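---
title: "Linear-scaling density-fitted Coulomb matrices with bubble hierarchies"
author: "bupo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-scaling density-fitted Coulomb matrices with bubble hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Coulomb matrix

$$J_{\mu\nu} = \sum_{\kappa\tau} D_{\kappa\tau}\,(\mu\nu|\kappa\tau)$$

is the classical electron–electron repulsion contribution to a Fock or
Kohn–Sham matrix for a density-like matrix $D$ over a Gaussian atomic-orbital
basis. Evaluated naively it scales quartically; with density fitting it
becomes quadratic; and because the number of *significant* shell pairs in a
molecule grows only linearly with size, a hierarchical multipole treatment of
the smooth long-range part can bring the build down to linear scaling. This
package implements that full chain in a self-contained, desk-scale engine:

* **RI-J** — the density is projected onto an atom-centered auxiliary basis
  in the Coulomb metric, $g_K = \sum_{\mu\nu} D_{\mu\nu} (K|\mu\nu)$, the
  metric equations $M c = g$ with $M_{KL} = (K|L)$ are solved by pivoted
  Cholesky, and $J_{\mu\nu} = \sum_K c_K (K|\mu\nu)$.
* **Split-RI-J** — the same numbers, but the rate-determining contractions
  run in the Hermite-Gaussian basis: products of basis functions are expanded
  exactly over Hermite Gaussians via McMurchie–Davidson E-coefficients, the
  auxiliary vector and the Hermite Coulomb matrix are formed through Hermite
  repulsion integrals $R_{tt'}$, and everything is back-transformed at the
  end. `split_rij_J()` agrees with `rij_J()` element-wise to $10^{-12}$.
* **RI-BUPO-J** — the linear-scaling build. Shell pairs and auxiliary shells
  are grouped into spheres ("bubbles") that strictly enclose every member
  *including its real-space extent*, bubbles nest recursively into a
  hierarchy ending in one top-level sphere, multipole moments are aggregated
  at the bottom and up-translated with increasing order, and every
  interaction is routed either through one real multipole contraction
  (far field) or through analytic three-index integrals (near field).

A non-fitted variant (`bupoJ_fullJ()`, four-index near field) is kept for
small systems and doubles as a second oracle family.

## Multipole machinery

All moments are *real scaled solid harmonics*
$\tilde R_\ell^m(\mathbf r) = r^\ell P_\ell^m(\cos\theta)e^{im\varphi}/(\ell+m)!$,
converted to real combinations by the standard unitary transform. The
symmetric scaling makes the translation matrix coefficient-free — its entries
are scaled regular solids of the displacement, lower triangular in $\ell$
with unit diagonal — and keeps every coefficient bounded up to the absolute
order cap of 44, so no factorial overflow can occur. The far-field coupling
of two moment vectors is $M_P^{\mathsf T}\, T^{PQ} M_Q$ with
$T^{PQ}$ built from scaled irregular solids of $Q-P$; both $T$ and the
translation matrix $W$ are assembled once as real matrices, so a far-field
contribution costs two real matrix products. The sign and phase conventions
are pinned by point-charge oracles in the test suite (monopole, dipole,
translation and rotation identities).

Three expansions terminate exactly and are exploited as such: an auxiliary
shell about its own atom (only $\ell = \ell_K$ survives), a primitive pair
about its Gaussian-product point (terminates at $\ell_\mu+\ell_\nu$), and a
one-center contracted pair (likewise). Exactness on one side of every
far-field contraction keeps the expansions short; the non-terminating side
(contracted pair centers, translated bubbles) is what the order parameters
control.

## Extents and the near/far gate

A multipole approximation is only safe if the two charge distributions do
not overlap, which for Gaussians requires an *extent*: a radius beyond which
the distribution is guaranteed below a threshold `T_sphere`. For a single
(auxiliary) shell the extent is the outermost radius where the radial
envelope $\sum_k |c_k| r^\ell e^{-\alpha_k r^2}$ (times the spherical-harmonic
bound $\sqrt{(2\ell+1)/4\pi}$) crosses `T_sphere` — rigorous, found by
bracketing and bisection. For a shell pair, two virtual walkers start outside
the two single-shell spheres on the line connecting the centers and scan
inward in fixed 0.01 Bohr steps until the axial bound on the pair magnitude
first exceeds `T_sphere`; the extent is the larger distance of the two stop
points from the exponent-weighted pair center, floored at 2 Bohr (a safety
measure for very tight core pairs). Defined this way the extent *shrinks*
as two shells separate, whereas the literature definition
(`baseline_extent_primitive()` / `baseline_extent_contracted()`, kept as comparison baselines) grows with
distance — on separated pairs by a factor of 2–3 over the walker value.
The axial product of per-shell envelope bounds is used for $\ell>0$ shells
(an upper bound, hence safe); the exact spherically averaged pair shape is
deliberately not reconstructed.

The gate itself: object and bubble interact via multipoles iff
$|C_{\rm obj}-C_{\rm bub}| \ge R_{\rm allow}\,( \mathrm{ext}_{\rm obj} + r_{\rm bub})$,
boundary inclusive, with $R_{\rm allow}=1$ (an additive-margin reading is
available as `R_allow_mode = "offset"` for experiments; the ratio reading is
the default because it is the form under which $R_{\rm allow}\ge 1$
guarantees a convergent expansion). Setting `R_allow = Inf` disables the far
field entirely, which collapses every builder onto its analytic twin — the
test suite asserts this to $10^{-12}$.

## Bubbles

Bottom-level bubbles are formed by a deterministic balanced k-means:
farthest-point seeding starting from the object nearest the centroid, fixed
iteration cap, lowest-index tie-breaks, and a single splitting pass for
clusters exceeding twice the target population (`TargetDim1`, default 150
objects). The bubble radius is
$\max_m(|c_m - C| + \mathrm{ext}_m)$, so no density can leak past the
boundary — the property that distinguishes bubbles from boxes, and the
reason the method is rotationally invariant where boxing schemes are not.
One caveat: the clustering re-runs on rotated coordinates, and floating-point
near-ties can repartition the bubbles, so the residual orientation dependence
of the energy equals the multipole accuracy of the chosen settings rather
than zero. The tests assert $10^{-10}$ Hartree invariance at high-order
settings, where repartitioning effects vanish below that bound; at the
production defaults the residual is of the order of the overall multipole
accuracy (about $10^{-9}$ on the study chains). Bubbles combine into
superbubbles of about `TargetDim2 = 3` children per level until one
top-level bubble encloses the system (hard cap 20 levels). Centroids are
unweighted; weighting members by extent was considered and rejected as an
unforced complication. Objects whose extent exceeds `diffuse_cutoff`
(20 Bohr) go to a throwaway bubble that is always near field, so diffuse
functions cannot poison the locality of the rest.

In the J-assembly step the auxiliary hierarchy uses *atomic* bubbles (all
auxiliary shells of an atom in one sphere): their bottom-level expansions
terminate exactly, which is the winning combination together with
contracted-center pair moments (`step2_pair_multipoles = "contracted"`; the
exact-but-verbose per-primitive option is available behind the flag).

## Parameters, defaults, and why

* `Lmax_step1 = 10`, `Lincr1_step1 = 6` — shell-pair bubble expansion order
  and first up-translation increment for the auxiliary-vector step.
* `Lmax_step2 = 6`, `Lincr1_step2 = 10` — contracted-pair order and the
  (necessarily large) first up-translation from exact atomic bubbles.
* `Lincr2 = 10` — later up-translation increments, both hierarchies. At
  desk scale the far-field error is dominated by the near-top-level bubbles,
  whose content nearly fills their radius at the marginal gate distance;
  increments of 10 put that error below the $10^{-8}$ Hartree floor while
  adding no measurable cost (high-level interactions are few). Incremental
  updates run at the reduced set (6, 4, 3).
* `T_sphere = 1e-8` — the extent threshold. This is the safety margin the
  gate converts into far-field accuracy; the conservative choice costs a
  modest growth of the near field and buys roughly an order of magnitude in
  the energy error at fixed multipole orders.
* `T_screen = 1e-10` (multipole coefficient screening), `Thresh = 1e-10`
  (Schwarz skipping against `PKMAX`, the per-bubble maximum of
  $K_{IJ}\max|D_{IJ}|$), `prescreen = 1e-12` (primitive-pair
  Gaussian-product survival), `R_allow = 1`, `TargetDim1 = 150`,
  `TargetDim2 = 3`, order cap 44, at most 20 levels, full rebuild every 10
  driver iterations with the accurate settings (`accurate_rebuild = TRUE`).

Numerical choices elsewhere: the Boys function uses the ascending series
with downward recursion below $T = 45$ and the asymptotic value with upward
recursion above; the pivoted-Cholesky solve drops pivots below $10^{-12}$
of the largest and verifies the residual; hierarchy descent takes the first
allowed ancestor bubble and excludes its descendants, so an exhaustive audit
can (and does) verify that every interaction is handled exactly once;
far-field contributions accumulate in the spherical AO basis while the
Hermite-basis organization is exercised by the Split-RI-J path.

## The synthetic benchmark systems

`make_chain()` builds quasi-linear chains of repeated units: single heavy
atoms on a line, or a pseudo-peptide unit of four heavy atoms plus two
hydrogens arranged off-axis and twisted by 100 degrees per unit with a rise
of 2.8 Bohr — a crude helix with the rise of an alpha-helical residue.
`toy_basis()` supplies a compact contracted s/p orbital basis and a matching
uncontracted s/p/d auxiliary basis whose walker extents land in the few-Bohr
range at bond-length spacings, the regime of production Gaussian bases.
`make_density()` provides a superposition-of-atomic-guesses density
(diagonal, equal occupation within every shell — hence exactly invariant
under rigid rotations, which is what makes the rotation tests clean) and a
seeded random symmetric positive semi-definite mode.

The study sizes used by the tests and the acceptance script: a 16-unit
helical chain (96 atoms, 288 basis / 608 auxiliary functions) for the
accuracy and convergence studies, 8/16/32-unit linear chains for the
scaling witness, and compact fragments of at most 10 atoms for the oracle
equivalences. These sizes were chosen as the smallest systems in which the
far field does substantial work (about 90% of batches leave the near field
on the chains) while brute-force oracles remain computable.

What the generator does *not* emulate: real nuclear charges and SCF-consistent
densities (the guess density stands in for the model-potential guess),
basis-set linear dependence, diffuse augmented sets, and 3-dimensional
globular topologies. Passing tests therefore demonstrate the mechanics of
the algorithm — extents, gates, hierarchies, translation, screening,
incremental rebuilds — at chemical-magnitude inputs, not production DFT
energetics.

## Known limitations

* Angular momenta up to $\ell = 5$ per shell; higher values error out.
* Four-index paths are capped (`eri4_cap`) and intended as oracles.
* No exchange, no exchange–correlation, no SCF convergence machinery,
  no gradients, no periodic boundary conditions, no parallelism.
* The walker extent is an axial upper bound for $\ell>0$ shells; it is safe
  but can overshoot slightly for strongly polarized pairs.
* Energy differences of about $10^{-13}$ of the total Coulomb energy are at
  the summation-order noise floor; assertions below that are meaningless.

## Reproducing the numbers

`scripts/acceptance.R --seed <s> --out <path>` re-runs the whole pipeline —
oracle equivalences, terminating-expansion exactness, the 16-unit-chain
error decomposition, extent monotonicity, the linear-scaling witness,
rotation invariance, and the hierarchy audit — and writes every measured
quantity to JSON. The test suite (`tests/testthat`) contains the same checks
plus the per-module oracles (quadrature Boys values, closed-form and
Gauss–Hermite ERI references, point-charge multipole identities).
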