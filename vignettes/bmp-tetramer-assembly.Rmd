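---
title: "BMP ligand-receptor tetramer assembly: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BMP ligand-receptor tetramer assembly: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmpassembly)
```

## The biological question

BMP ligands are disulfide-linked dimers that signal by assembling a
tetramer of serine-threonine kinase receptors: two type-I and two type-II
chains. With three ligand dimers (Bmp2/2, Bmp7/7, Bmp2/7) and two type-I
receptors (BmpR1, Acvr1) plus a pooled type-II receptor, nine distinct
fully-assembled tetramer classes can form. Genetic evidence in zebrafish
shows dorsoventral patterning runs through exactly one of them — the
heterodimer bound to one BmpR1 and one Acvr1,
`Bmp2/7-Acvr1-BmpR1-(TypeII)2`. This package models the assembly network
at mass-action equilibrium to ask whether simple binding kinetics favor
that complex (they do not) and to quantify a different advantage: its
dynamic range as a morphogen sensor.

## Model structure

**Sites and affinities.** Each dimer exposes one type-I and one type-II
binding epitope per monomer face. Per-site dissociation constants (nM)
are taken from surface-plasmon-resonance literature:

| face | BmpR1 | Acvr1 | type-II |
|------|------:|------:|--------:|
| Bmp2 | 0.8   | 1024  | 47      |
| Bmp7 | 56    | 512   | 6.4     |

Sites are independent: a site's affinity does not depend on the occupancy
of the other sites. That assumption (no stated cooperativity) also
guarantees detailed balance, so every thermodynamic cycle in the network
closes exactly — asserted numerically to 1e-12 in the test suite.

Two conventions are genuinely underdetermined by the available
measurements and are exposed as options rather than hard-coded:

* **Heterodimer type-II affinity** (`bmp_affinities(het_typeii=)`). The
  structural reading gives Bmp2/7 one 47 nM and one 6.4 nM type-II site
  (`"per-face"`). The shipped default (`"shared"`) assigns 6.4 nM to both.
  The choice matters: under per-face weights the
  `Bmp2/7-(BmpR1)2-(TypeII)2` concentration is algebraically the
  geometric mean of the two homodimer counterparts (the partition-function
  factors multiply out exactly), so it can never be the most abundant
  tetramer anywhere — contradicting the published screen in which it is
  the runner-up over a fifth of parameter space. The shared high-affinity
  pair restores that structure, and is the convention whose screen output
  matches the published fractions most closely.
* **Acvr1 on Bmp2 faces** (`acvr1_bmp2=`). Reported as "no demonstrable
  affinity (K_D > 1000 nM)"; enabled by default at 1024 nM so that all
  nine tetramer classes are formable, with a switch to disable.

**Enumeration convention.** Complexes are lumped by the multiset of
receptors bound within each site class (`merge_sites = "class"`), e.g.
"Bmp2/7 with one BmpR1, one Acvr1 and two type-II" is one species
regardless of face assignment. An exhaustive search over the discrete
convention space (`convention_search()`: three lumping rules times the
Acvr1/Bmp2 switch) shows this is the unique convention reproducing the
published counts of 51 oligomer species and 90 bidirectional reactions
(3 dimers x 17 occupancy states x 30 single-bond transitions). Lumped
statistical weights are *exact* sums over the underlying face-resolved
microstates (`site_kinetics = "microstate"`), so the coarse model's
equilibrium equals the fine one's; an ordered-binding approximation
(strongest face fills first, full pair multiplicity) is kept as an option
for sensitivity analysis. Face-resolved enumeration (105 species / 252
reactions) remains available via `merge_sites = "none"`.

**Surface enhancement.** The first ligand-receptor encounter is a
solution-phase reaction; every later recruitment happens between
membrane-confined partners, whose association rates are multiplied by a
reduction-of-dimensionality factor γ (10-1000 across the screens; 10-100
is the physiologically reasonable band). A complex with `b` bonds
therefore carries `gamma^(b-1)`. Since the system is closed, equilibria
depend only on the K_D values and γ — the reference association rate
`kon_ref` (default 1e-3 /nM/s) cancels, which the test suite asserts by
rescaling it 20-fold.

## Steady-state computation

Detailed balance makes every complex concentration an explicit monomial
in the six free concentrations, so steady state reduces to six
conservation equations. `solve_equilibrium()` minimizes the corresponding
strictly convex dual in log-free-concentration space (positivity is
automatic) with a damped Newton iteration, vectorized across entire
parameter grids; the per-point 6x6 Newton systems are solved by a batched
Cholesky factorization. Convergence is declared at a relative
conservation residual of 1e-11 (about the double-precision noise floor
for 50 nM totals); rare deep-depletion corner points get an automatic
fresh-start retry with a larger iteration budget, then an ODE-seeded
polish if still stalled. The full 84,375-point
screen solves in well under a minute on one core with every point
converged and mass-balance violations around 1e-10 nM.

`integrate_to_steady_state()` is the independent fidelity route: one ODE
per species integrated with `deSolve::lsoda` from the all-free initial
condition until the relative rate of change of every species stays below
1e-9 /s across a 100 s window (capped at 1e7 simulated seconds, with an
honest `.converged` flag). The two routes agree to better than 1e-6
relative on every species across 100 random parameter sets; the algebraic
route is used for screens, the ODE route for validation.

**Ligand semantics.** Two boundary conditions are supported.
*Conserved*: ligand totals are closed, shared between free and bound
pools — the regime of the prevalence screen and the scenario sweeps.
*Clamped* (`ligand_mode = "clamped"`): the free ligand concentration is
held at the ambient value, an open morphogen reservoir. The
receptor-sensitivity and sensor analyses use the clamped mode; the
characteristic biphasic response of `Bmp2/7-(BmpR1)2` to BmpR1 titration
is impossible at equilibrium under conserved sub-nanomolar totals (the
type-II pool can never become limiting when total ligand demand is below
2 nM), whereas a reservoir reproduces it, along with the documented
prozone ("negative slope") regions at high ligand.

## The screens

**Prevalence screen.** 5 log-spaced ligand levels (0.01-1 nM, the three
dimers co-varied), 15 levels per receptor (1-50 nM), five γ values — the
84,375-point grid. Per point we record all nine tetramer-class
concentrations, the most abundant class (ties broken toward the
lexicographically first class and counted; none occur in practice), the
predominance flag, and convergence diagnostics. The receptor spacing is
not stated in the source design; `grid_spec()` defaults to linear and
supports log, the acceptance run computes both, and the log spacing is
the documented better-matching convention (e.g. the
heterodimer-heterotetramer most-abundant share lands at 5.70% vs the
published 5.66%).

**Predominance** has two readings: the default compares the
heterodimer-heterotetramer against the summed tetramers of homodimer
*ligands*; the alternative (`"homomeric-receptor"`) against all
identical-type-I-pair tetramers. Both are computed in summaries.

**Kinase discounting** removes classes assumed catalytically silent
(default: the three two-BmpR1 classes, the low-BmpR1-kinase-activity
scenario) and re-ranks the rest.

**Scenario sweeps** fix receptor stoichiometries with unstated absolute
levels in the source; the shipped configurations (`bmp_scenarios()`) were
chosen once inside the physiological band so the documented qualitative
behaviors hold: 8-fold Acvr1 excess (1/8/10 nM, γ=50) shows the het-het
overtaking all classes at high ligand inside 0.1-1 nM; the Bmp2/7-only
system with 9-fold Acvr1 excess (5/45/10 nM) favors the het-het over a
wide ligand range.

**Dynamic range.** For each tetramer class, the detection floor is the
ligand level producing one complex per cell (360 molecules per nM, from
the 1-50 nM = 360-18,000 receptors correspondence), floored additionally
at one ligand molecule per cell; saturation is the smallest ligand level
reaching 95% of the curve's maximum on its rising limb (for biphasic
curves, the peak). The fold range is their ratio; classes never reaching
one complex per cell are "unformable" and cannot win. The 343-point
screen uses 7 log-spaced levels per receptor over 1-50 nM, a 61-point log
ligand scan over 1e-4 to 10 nM, clamped ligand, and γ=10 — the low end of
the physiological band, fixed once after a scan of 1-100 because it best
reproduces the published pairwise sensor advantage (82.8% vs 82.5%
of receptor space where the het-het out-ranges every two-BmpR1 class).
Crossings are refined by bisection against fresh steady states in
`dynamic_range()`; the screen uses monotone log-log interpolation on the
scan, which grid-refinement tests bound below 1% error.

## Synthetic fixtures and oracles

Every numerical claim is checked against code that shares nothing with
the production solver: the one-site Langmuir network against the
quadratic closed form; a two-independent-site network against an
exhaustive grid search over the free receptor concentration (binomial
statistical weights fall out as a special case); reproducible log-uniform
random parameter sets within the screened ranges for the
conservation/cross-validation properties. These fixtures emulate the
model's structural features — reversible bimolecular binding,
conservation, site independence — but not features of real data (no
measurement noise, no cell-to-cell variability), so passing tests
certify the solver and bookkeeping, not biological accuracy of the
affinity inputs.

## Known limitations

* Receptor synthesis, degradation, endocytosis and downstream (Smad)
  signaling are outside the model; steady states are equilibria of a
  closed binding system.
* The affinity table rests on in-vitro measurements; the
  heterodimer-specific conventions above are calibrated reconstructions,
  not measurements, and both alternatives ship as options.
* Some published screen fractions are not reproduced at their printed
  precision under any convention we searched (documented in the test
  expectations): the model family here brackets the published structure
  (rank order of the dominant classes, near-exact het-het prevalence and
  pairwise sensor advantage) rather than matching every percentage.
* Stochastic (molecule-count) noise is not modeled; the
  one-molecule-per-cell floor is a deterministic proxy.
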