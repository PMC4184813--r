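---
title: "Refining NMR structures without NOE data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining NMR structures without NOE data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NMRefine)
```

## The idea

NOE-derived distance restraints are the workhorse of NMR structure
calculation, but NOE tables are ambiguous, noisy and often unavailable for
deposited structures. NMRefine refines a protein structure *without* any
experimental distance data: it reads the inter-hydrogen distances off the
structure itself, converts them into flat-bottom distance restraints, and
re-anneals the structure under those restraints plus a knowledge-based
torsion-angle potential and a base force field. The self-derived restraints
hold the global fold in place while the other energy terms repair local
geometry; the flat-bottom width `w` controls how much freedom the structure
has to move.

## Restraint generation

Hydrogens are grouped into chemical-equivalence groups by geometry: each
hydrogen attaches to its nearest heavy atom within 1.2 &Aring; (methyl = 3,
methylene = 2, otherwise singletons). A pair of groups becomes a restraint
when **any** member hydrogen-hydrogen distance is below the 7 &Aring; cutoff
(strictly; ties excluded for determinism). Two conventions supply the
equilibrium distance `d`:

* **r6 summation** ("S1"): `d = (sum_i r_i^-6)^(-1/6)` over all member
  pairs, mimicking how NOE intensities average over indistinguishable
  hydrogens. Member distances beyond the cutoff still enter the sum.
* **shortest distance** ("S2", the default): `d = min_i r_i`.

The r6 value never exceeds the shortest distance, and many member
combinations reproduce the same r6 value — which is exactly why the
shortest-distance convention drifts less at width 0 and is the default.
Groups sharing a heavy atom are excluded by default (`"same-heavy"`);
nothing else is, because the goal is to freeze the given conformation.
Restraints come from a single chosen model (default 1) of an ensemble.

## The flat-bottom potential

Each restraint contributes

* 0 on the flat bottom `[r_min, r_max] = [d - w/2, d + w/2]`
  (`r_min` clamped at 0),
* a quadratic wall `k x^2` for displacements `x` up to `rsw` beyond either
  edge,
* a soft asymptote `A + B / x^SE + f x` beyond that.

`A` and `B` are solved in closed form from value and slope matching at
`x = rsw`:

```
B = (f - 2 k rsw) rsw^(SE+1) / SE
A = k rsw^2 - B / rsw^SE - f rsw
```

Defaults are `SE = 1`, `f = 1`, `k = 1/2`, `rsw = 3`, giving `A = 7.5`,
`B = -18`. The asymptote's force tends to the constant `f` instead of
growing linearly, so a badly violated restraint can never exert a
destabilizing force during dynamics — that bounded-force property is the
point of the construction. Both sides share the shape parameters by
default; the lower asymptote only becomes reachable when `r_min > rsw`,
which for typical `d < 7` &Aring; and `rsw = 3` is rare. The restraint sum
is scaled by 10 in the total energy:

```
E_total = E_base + E_torsion + 10 * E_flat
```

Forces flow through the effective distance by the chain rule: for r6,
`d_eff` is smooth and every member pair feels
`U'(d_eff) d_eff^7 r_i^-7`; for the shortest-distance convention only the
currently minimal pair feels the force (the minimizing pair can switch
discontinuously between steps, which annealing tolerates).

```{r flatbottom}
p <- flatBottomParams(d = 5, w = 4)
fbEnergy(c(5, 8, 12), p)     # flat bottom, quadratic wall, asymptote
fbGradient(c(8, 1000), p)    # wall slope 2k*x; asymptotic slope -> f
```

## Torsion-grid potential

A knowledge-based statistical torsion potential is evaluated (never
derived here) from per-residue-class 2D grids over the torsion pairs
phi-psi, phi-chi1, psi-chi1 and chi1-chi2, with 21 classes (20 amino acids
plus pre-proline: a residue directly preceding a proline). Grids are
periodic over 360 degrees and interpolated bilinearly; forces use the
analytic dihedral gradient. Bilinear interpolation is exact at nodes and
C0 across cells; its gradient is piecewise constant per dimension, which
is adequate under a thermostat and keeps evaluation cheap. Tables load
from a plain-text format (`table CLASS PAIR-KIND BIN` headers plus matrix
rows); `syntheticTorsionTables()` builds cosine-well surfaces with known
minima so the evaluator is testable without any statistical derivation.

## Base force field

A full molecular-mechanics energy is deliberately out of scope; the
refinement engine accepts any energy/forces provider. The shipped default
is *self-parameterized*: harmonic bonds (`k_bond = 300` kcal/mol/&Aring;&sup2;,
energy `k (r - r0)^2`) and angles (`k_angle = 50` kcal/mol/rad&sup2;) at their
values in the structure it is built from, plus a soft-core repulsion
(`k_rep = 50`) between non-bonded, non-1-3 heavy pairs with per-pair onset
`min(3.2, input distance)`. The structure it is parameterized on is an
exact zero of energy and force. This keeps covalent geometry and excluded
volume sane during annealing while remaining fully reproducible; it is not
transferable and it does not model electrostatics or solvation.

One consequence matters for the synthetic experiments: the base field
should be parameterized on a structure with *sane* geometry. Gaussian
coordinate noise breaks bond lengths, and harmonic terms parameterized on
noise anchor the noise. In the recovery experiments below the base field
is therefore built from the unperturbed reference — the same structure the
restraints come from — which mirrors how a real force field's minima sit
at ideal geometry regardless of the input conformation.

## Simulated annealing

The staged protocol is: initial minimization; heating from 100 K to 500 K
over 1600 MD steps (linear ramp); annealing at 500 K for 2000 steps;
linear cooling to 25 K over 4000 steps; 100 final minimization steps.
2000 annealing steps is the default because longer annealing (5000 or
10000 steps) does not change the outcome appreciably; both remain valid
inputs. Dynamics are velocity-Verlet with a 2 fs timestep, per-element
atomic masses, and a per-step velocity-rescaling thermostat to the staged
target temperature; minimization is steepest descent with an adaptive step
capped at 0.2 &Aring; per coordinate. Initial velocities are
Maxwell-Boltzmann at the heating start temperature from the schedule's
seed, after which everything is deterministic: the same configuration and
seed reproduce the trajectory exactly. Units are kcal/mol, &Aring;, amu
and ps (1 kcal/mol/&Aring;/amu = 418.4 &Aring;/ps&sup2;,
kB = 0.0019872 kcal/mol/K).

`widthSweep()` refines a fresh copy of the input once per width
(default 0-10 &Aring; in 1 &Aring; steps) and ranks results by the total
score, ties to the smaller width. The recommended single-run width is
4 &Aring;, the middle ground where fold-retention scores (similarity,
violations — better at small widths) balance local-quality scores (better
at large widths).

## Quality assessment

* **Total score**: `sum_i w_i (x_i - bad_i) / (good_i - bad_i)` over the
  metrics present in both the observed vector and the score table; the
  highest total marks the best structure. External validator outputs
  (clash, nDOPE, dDFIRE, Ramachandran percentages, WHAT_CHECK Z-scores)
  are *inputs* read from a metrics file. The shipped
  `score_table_default.tsv` is a documented default, **not** a published
  calibration; users with a calibrated table should supply it.
* **NOE violations**: per restraint `max(0, d_eff - upper)` with `d_eff`
  by r6 summation over the selection pair; mean over all restraints by
  default (mean over violated only as an option — the conventions differ
  and both are exposed); counts above 0.5 / 1.0 / 2.0 &Aring;.
* **Backbone similarity**: Kabsch RMSD (SVD, proper rotation), GDT-TS
  (cutoffs 1, 2, 4, 8 &Aring;), GDT-HA (0.5, 1, 2, 4 &Aring;), TM-score
  with `d0 = 1.24 (L-15)^(1/3) - 1.8` (fallback 0.5 for L &le; 15). The
  superposition search is an iterative seed-and-extend over contiguous
  windows — a documented approximation of the exhaustive LGA enumeration
  that is exact for identical and rigidly moved structures.
* **Secondary structure**: 3-state (H/E/C) match percentages, overall and
  per class. Assignments are expected as input (8-state assignments
  reduced upstream: H,G,I to H; E,B to E; else C); the built-in
  `assignSS()` is a coarse phi/psi rule for synthetic fixtures only.

## The synthetic study system

`buildPolypeptide()` constructs ideal-geometry poly-alanine chains
(bonds/angles at standard ideals, helix phi = -57, psi = -47, L
configuration) with amide, alpha and methyl hydrogens;
`perturbStructure()` adds seeded per-coordinate Gaussian noise. The
default test system — a 10-residue helix, sigma = 0.8 &Aring; noise,
restraints from the unperturbed structure, a 10x-shortened schedule —
keeps every experiment under a minute per condition on one CPU. What this
emulates is the *mechanics* of refinement: restraint recovery, width
response, energy bookkeeping, determinism. What it does not emulate:
real NMR ensembles' correlated coordinate errors, side-chain diversity
(chi tables are exercised separately), solvent effects, or the
conformational strain of real misfolded regions — so passing tests
demonstrate the machinery, not benchmark-level accuracy on deposited
structures.

## Numerical choices and degenerate inputs

* Cutoff comparisons are strict (`<`); pair order is deterministic, so a
  build is bit-reproducible.
* The potential is evaluated as a total function on r &ge; 0; branch joins
  are C0/C1 by construction (verified to 1e-9 / 1e-6 in the tests), C2
  discontinuities at the joins are inherent and harmless.
* Zero-width bottoms, clamped `r_min`, empty restraint sets, hydrogens
  with no heavy atom in range (orphans), and residues with missing
  torsion atoms are all handled explicitly (warning, clamp, empty result,
  orphan singleton, skipped term respectively).
* Energy divergence during dynamics (non-finite total) aborts with the
  stage and step in the message.

## Known limitations

* The base force field is a stand-in: no electrostatics, no solvation, not
  transferable. Plug a real engine via the provider interface for
  production-quality local geometry.
* Shortest-distance restraint forces act on one member pair at a time.
* GDT/TM use a heuristic superposition search; scores can be marginally
  below the exhaustive-search values for pathological decoys.
* Tables for the torsion potential must be supplied; only their evaluation
  is implemented here.
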