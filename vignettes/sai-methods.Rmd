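---
title: "Serial atom insertion at desk scale: models, schedules, estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial atom insertion at desk scale: models, schedules, estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saisolv)
```

## The problem

The absolute solvation free energy (ASFE) of a solute is the free energy of
transferring it from an ideal-gas phase into solution.  Alchemically it is
obtained from an annihilation cycle: all nonbonded interactions of the solute
— intermolecular *and* intramolecular — are switched off once in solution and
once in vacuum, and

$$\Delta G_{\mathrm{solv}} = \Delta G^{\mathrm{vac}} - \Delta G^{\mathrm{aq}}
  + \Delta G_{\mathrm{LRC}},$$

where both legs run in the annihilation direction (physical state to fully
decoupled dummy) and $\Delta G_{\mathrm{LRC}}$ restores the Lennard-Jones
dispersion the aqueous leg never sees because of the finite cutoff.

Serial atom insertion (SAI) is a way of building the intermediate states of
this path without soft-core potentials: rather than dragging every
interaction through a continuous coupling parameter, atoms are switched off
*serially*, one heavy atom per intermediate state, after the charges and the
hydrogen Lennard-Jones terms have been removed in a few global scaling steps.
Every intermediate state is an ordinary, fully specified parameter set that
any plain simulation engine can sample; the estimator (MBAR) only needs the
reduced energies of every sample re-evaluated under every state.

`saisolv` implements this workflow end to end at desk scale: toy
solute–water systems small enough that every estimator can be validated
against closed forms, brute-force sums and an independent reference route on
one CPU in minutes.

## The annihilation schedule

`build_schedule()` emits the state sequence in four blocks, with the
default factors of the protocol it reproduces:

1. **Charge block** — partial charges of all solute atoms scaled by
   1.0, 0.6, 0.3, 0.0 (four states; the first is the physical state).
   Uniform scaling preserves the net charge of neutral solutes exactly.
2. **Hydrogen block** — Lennard-Jones $r_{\min}$ and $\varepsilon$ of *all*
   hydrogens jointly scaled by 0.5 then 0.0 (two states, never per atom).
3. **Heavy-atom block** — one state per heavy atom, switched off in removal
   order, except the last heavy atom, which is removed in two states
   (factors 0.5, 0.0).
4. **Terminal state** — one duplicated, fully decoupled bookkeeping state.

The published description of the blocks yields $4 + 2 + (n_\mathrm{heavy}-1)
+ 2 = 14$ states for a seven-heavy-atom solute, while the printed count for
toluene is 15.  We resolve this by emitting the terminal all-zero state by
default (`emit_terminal_state = TRUE`): a duplicated endpoint state is
harmless to MBAR (its free energy difference to the true endpoint is exactly
zero) and makes the seven-heavy-atom count 15.  Setting the flag to `FALSE`
gives the strict block count.

### Heavy-atom removal order

The order in which heavy atoms disappear is not prescribed beyond the intent
that the still-interacting region stays chemically sensible.  The rule used
here keeps the remaining heavy-atom graph connected at every step and peels
the molecule from the periphery inward: among the remaining atoms whose
removal leaves the remainder connected (the non-cut vertices), remove the
one with the smallest current degree, breaking ties by smallest original
degree and then by ascending index.  For a linear chain C1–C2–C3 this gives
C1, C3, C2 (both terminal atoms before the interior atom); for a ring, where
no leaf exists, the ring is opened at the lowest-index atom and pruning
continues in index order.  The original-degree tie-break is what prefers a
terminal atom over an atom that only *became* terminal through earlier
removals; without it the centre of a star could disappear before its last
spoke.

## The toy systems

The fixture generators are first-class, tested code: they define the study
conditions rather than being a convenience.

* **Solutes** (`make_toy_solute`): connected heavy-atom graphs (chain, ring
  — a six-ring with substituents appended, so `(7, 8, "ring")` is
  toluene-like — or star), hydrogens attached round-robin within a valence
  of four.  Partial charges are drawn uniformly and recentred to sum to zero
  *exactly*; Lennard-Jones parameters stay in plausible small-organic ranges
  (heavy atoms $\varepsilon \in [0.05, 0.2]$ kcal/mol, $r_{\min} \in [3.0,
  4.5]$ Å; hydrogens $\varepsilon \in [0.02, 0.05]$, $r_{\min} \in [2.0,
  2.5]$ Å).  Bonds are harmonic springs ($k = 300$ kcal/mol/Å$^2$ at the
  constructed lengths); there are no angle or torsion terms, and 1-2/1-3
  pairs are excluded from the intra-solute nonbonded sum.
* **Water** (`toy_water`): a rigid three-site monomer (one LJ oxygen site,
  two charged hydrogens, O–H 0.9572 Å, H–O–H 104.52°) moved as a rigid
  body.  The numbers are TIP3P-like, but the model is deliberately *not*
  claimed to be TIP3P-faithful — it only needs to behave like a polar,
  hydrogen-bonding liquid.
* **Cutoffs and boxes.**  The full-scale protocol tapers LJ interactions
  between 10 and 12 Å in boxes of at least 26 Å holding hundreds of waters.
  That is cluster-scale.  The toy systems instead use $r_{\mathrm{on}} = 4$ Å,
  $r_{\mathrm{off}} = 5$ Å in 10–12 Å boxes of 20–40 waters, preserving the
  structure of the problem (a switched cutoff well shorter than the box,
  with the box-edge guard $L \ge 2 r_{\mathrm{off}}$ enforced) at a size
  where repeat-based statistics converge in minutes.  Electrostatics are
  minimum-image Coulomb with the same potential-switch taper as the LJ
  terms; there is no Ewald summation, so the toy water's dielectric response
  is not quantitative.  This is acceptable because the estimators, not the
  electrostatics model, are under test: both free energy routes see the same
  Hamiltonian.

## Sampling

`mc_sample()` is a Metropolis Monte Carlo sampler: single solute-atom
translations, rigid whole-solute translation+rotation, rigid water
translation+rotation, and optional isotropic $\ln V$ volume moves for
constant-pressure runs (303.15 K and 1 atm are the default thermodynamic
state).  Step sizes are auto-tuned toward a 0.2–0.6 acceptance rate during
a discarded tuning phase and then frozen, so production sampling satisfies
detailed balance.  Any valid Boltzmann sampler would do — the estimators
consume configurations only — and a sampler is preferable at this scale to
a dynamical integrator because it needs no constraints, thermostats or
minimisers.  A fixed seed gives a bit-identical trajectory; repeat $r$ of a
calculation derives its seeds from `base_seed + r`.

Each per-state trajectory loses its first 25% to equilibration before
estimation (`discard_equilibration`, floor convention: a 10,000-frame run
keeps 7,500).  The defaults in `asfe_config()` (1,500 sweeps per state,
one frame kept every third sweep, four repeats) are the desk-scale
problem sizes used throughout the package's own validation; the acceptance
checks in `tests/testthat/test-acceptance.R` state their sizes explicitly.

## Estimators

**MBAR.**  `reduced_potential_matrix()` re-evaluates every retained frame
under every state: $u(x, k) = \beta U_k(x)$, plus $\beta p V(x)$ only for
frames that carry instantaneous volumes (vacuum legs never include the
pressure term).  `mbar_solve()` then finds the reduced free energies by
self-consistent iteration of

$$f_i = -\ln \sum_n \frac{e^{-u_i(x_n)}}{\sum_k N_k \, e^{f_k - u_k(x_n)}}$$

log-sum-exp stabilised and anchored at $f_1 = 0$, polished by Newton steps
on the convex MBAR objective, to $\max|\Delta f| < 10^{-10}$ (iteration cap
$10^5$; non-convergence raises an error carrying the overlap matrix).  The
overlap matrix $O_{ij} = \sum_n W_{ni} W_{nj} N_j$ is row-stochastic; any
adjacent-state overlap below 0.03 triggers a warning, the same signal the
full-scale workflow uses to flag under-sampled transformations.

Uncertainties follow the repeat protocol: four independent repeats, the
quoted error being their sample standard deviation.  A within-run bootstrap
of the solved MBAR (`mbar_bootstrap_stderr`, frame-level resampling within
each state) is available as a secondary diagnostic of the same quantity.

**TI reference route.**  `run_asfe_ti()` provides an independent path to
the same endpoints, mirroring the role of a traditional soft-core
reference calculation: a single coupling parameter $\lambda \in [0, 1]$
scales all solute-involving interactions with separation-shifted forms,
$U_{\mathrm{LJ}} = (1-\lambda)\,U_{\mathrm{LJ}}\big(\sqrt{r^2 +
\alpha\lambda}\big)$ and likewise for Coulomb ($\alpha = 5$ Å$^2$), which
removes the endpoint singularity.  The exact functional form of the
original soft-core implementation is not reproduced here — it does not have
to be: free energy is a state function, so any well-behaved path between
the same endpoints must give the same answer, which is precisely what the
two-route agreement check exercises.  21 equidistant $\lambda$ states are
sampled, the first 10% of each discarded as burn-in,
$\langle dU/d\lambda\rangle$ computed analytically per frame, and the
profile integrated by a natural cubic spline in closed form per segment.

A note on the spline: with *natural* boundary conditions (second derivative
zero at the endpoints) the integral is exact for straight lines but not for
general cubics — the boundary condition is wrong wherever the true profile
has curvature at $\lambda = 0, 1$.  At 21 equidistant points the residual
error for a smooth profile is of order $10^{-4}$ relative, far below the
statistical noise of any sampled profile; the tests therefore compare the
integrator against an independent natural-spline oracle at $10^{-8}$ rather
than asserting exactness on polynomials.

## The long-range correction

`analytic_tail()` evaluates the isotropic correction

$$E_{\mathrm{LRC}} = \frac{2\pi}{V} \sum_{a,b} N_a N_b \int
  \big[U_{ab}(r) - U^{\mathrm{switched}}_{ab}(r)\big]\, r^2 \, dr$$

per site-type pair, with the beyond-cutoff part in closed form (the
attractive $-2\varepsilon r_{\min}^6/(3 r_{\mathrm{off}}^3)$ tail plus the
$r^{-12}$ term) and the switch deficit on $[r_{\mathrm{on}},
r_{\mathrm{off}}]$ by adaptive quadrature at $10^{-10}$ relative tolerance.
Exact per-type sums are used rather than an average-dispersion-coefficient
approximation.  `lrc_correction()` takes the difference between the full
system and the same box with the solute removed — the dispersion the
aqueous annihilation leg is missing — which is negative for any solute
whose atoms are all attractive and grows in magnitude with solute size.

For constant-pressure trajectories, `a_posteriori_lrc()` re-evaluates the
analytic tail at every frame's instantaneous volume, discards the first
third of each run, averages, differences full against water box, and (with
three repetitions at distinct seeds) reports mean ± SD.  The influence of
the missing tail on the virial is deliberately ignored, exactly as in the
procedure this mirrors; the constant-volume limit (where the a-posteriori
estimate must collapse onto the analytic difference) is asserted in the
tests.

## Cutoff treatments

Four LJ treatments are implemented: the CHARMM potential switch (`VSWI`),
the OpenMM quintic smoothstep (`OMM_VSWI`), the Steinbach–Brooks force
switch (`VFSW`, energy-shifted below $r_{\mathrm{on}}$, force continuous at
$r_{\mathrm{on}}$ and zero at $r_{\mathrm{off}}$ — the implementation is
verified against those properties by finite differences rather than
trusting transcribed constants), and hard truncation (`NONE`).  Coulomb
interactions always use the potential-switch taper regardless of the LJ
kind, so that a comparison of ASFEs between `OMM_VSWI` and `VFSW` isolates
the LJ treatment — the comparison the switch-robustness check performs,
which should (and does, within statistical error) become treatment-
independent once the LRC is added.

## Design choices and limitations

* Atom indices are 1-based everywhere, as is idiomatic in R; the system
  file format declares this in its header.
* The system format is YAML with declared units and 17-significant-digit
  numbers, so write–load–write round trips are byte-identical and files
  are diffable.
* Charged solutes are accepted with a warning: uniform charge scaling
  changes the net charge of a non-neutral solute, and the benchmark this
  package mirrors contains neutral molecules only.
* The vacuum leg of a three-atom solute has no intra-solute nonbonded
  pairs at all (everything is 1-2 or 1-3); its annihilation free energy is
  exactly zero.  This is correct, not degenerate, and the test systems
  with hydrogens exercise non-trivial vacuum legs through their 1-4+
  pairs.
* What passing the toy-scale checks shows: the schedule bookkeeping, the
  estimators, the correction terms and the statistics layer are correct
  and internally consistent.  What it does not show: force-field accuracy,
  PME electrostatics, barostat dynamics, or the behaviour of real
  molecules — those belong to the full-scale campaign this package
  deliberately does not reproduce.
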