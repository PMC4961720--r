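---
title: "Descriptor-guided peptide design and chemical-shift conformational analysis"
author: "pepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-guided peptide design and chemical-shift conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscan)
```

## The problem

Short cationic/amphipathic peptides can kill bacteria by partitioning
into and disrupting their membranes.  A cheap first screen for such
activity is a handful of whole-sequence physicochemical descriptors; a
candidate can then be refined by scanning mutagenesis *in silico* before
anything is synthesised.  Once a peptide exists, solution NMR gives a
low-cost readout of its conformational preferences through secondary
chemical shifts.  `pepscan` implements both halves of that workflow for
peptides of roughly 5–50 residues: the descriptor panel and scanning
design, and the chemical-shift-deviation (CSD) analysis with NOE
restraint accounting.

## The descriptor panel

All six descriptors are compositional — they depend only on the residue
multiset, not its order — and are driven by plain-text residue scales
shipped with the package (`loadScale()`, `availableScales()`).

* **Boman index** (kcal/mol per residue): the mean over residues of the
  sign-inverted free energy of transfer from cyclohexane to water
  (Radzicka–Wolfenden hydration potentials).  Hydrophilic, H-bonding
  side chains score positive; a high mean flags protein-binding rather
  than membrane-seeking character.  Proline has no measured value and is
  set to 0 in the bundled scale.
* **GRAVY**: the grand average of Kyte–Doolittle hydropathy.
* **Wimley–White interface value** (kcal/mol): the *sum* — a
  whole-peptide partitioning free energy, not a per-residue average — of
  whole-residue transfer free energies from water to the POPC bilayer
  interface, using the charged Asp/Glu and neutral His variants of the
  scale.  Negative totals favour the membrane interface.
* **Net charge**: side chains only, `(#K + #R) − (#D + #E)`, His
  neutral, termini ignored.  No pH model is attempted.
* **Hydrophobic ratio** (%): residues in {A, C, F, I, L, M, V, W} over
  length, truncated to an integer percent.  Glycine is deliberately not
  counted as hydrophobic.
* **Molecular weight** (Da): average residue masses plus one water.
  The default is free termini, which is the convention of the published
  panels this package reproduces even where the peptide itself is
  C-terminally amidated; `cTerminus = "amide"` subtracts 0.9847 Da.

### Display truncation

Internally everything is double precision.  For display (and in
`designReport()`) values are *truncated toward zero* at the panel's
printed precision — Boman and interface values at 2 decimals, GRAVY at
3 — via `truncateToZero()`, which guards the floor with 1e-9 to absorb
binary representation error.  Truncation, not rounding, is used because
it is the convention the reproduced panels follow in the large majority
of cells (e.g. 17.23/13 = 1.3254 shown as 1.32, −25.30/15 = −1.6867
shown as −1.68); a few printed cells are instead rounded, which is why
comparisons against printed values in the test-suite accept agreement to
within one unit of the printed precision.

## Scanning design

`glycineScan()` substitutes every position in turn by glycine — the
side-chain-free probe residue — and tabulates the full panel plus deltas
against the parent.  `reactivePositions()` ranks positions by the
improvement of a chosen descriptor (Boman index by default, since the
design goal is antimicrobial potential) and returns the top *k*
including all ties with the *k*-th value; ties are real, because
composition-equal mutants score identically.

`enumerateCandidates()` then installs charged residues at the reactive
positions.  Two deliberate semantics:

* **Each alphabet residue is used at most once per candidate.**  The
  design question is "add one lysine and one aspartate", not "fill all
  positions with the single best residue" — under with-repetition
  semantics a double-aspartate variant would dominate the Boman ranking
  and the procedure would no longer model the intended chemistry.  The
  alphabet is a set of chemical groups to place, injectively, onto the
  candidate positions.
* **Deterministic tie-break.**  Candidates are generated with fewer
  substitutions first, position subsets ascending, alphabet residues in
  the user-given order, and ranking is a stable sort on the criterion.
  Composition-equal assignments (K@8+D@12 versus D@8+K@12) therefore
  rank in a reproducible order, with the user's alphabet priority
  deciding.

Identity substitutions are kept in scans (a glycine position scanned by
glycine is a parent-equal row, so every position appears exactly once)
but excluded from candidate enumeration, where they would duplicate
smaller candidates.  The ranking criterion is a parameter; nothing is
hard-coded to the Boman index.

## Chemical-shift-deviation analysis

`readShiftTable()` parses a small TSV dialect for assigned proton
shifts (three- or one-letter residues, atoms `NH`/`aCH`/`bCH`/`gCH`/
`other:<text>`, `#!` metadata header) and cross-validates every record
against the peptide sequence.  `csdAlpha()` computes per-residue
secondary shifts Δδ(i) = δ_obs(i) − δ_rc(residue i) for the αCH proton,
using a bundled aqueous random-coil reference table (Wishart-style
peptide values, shipped as versioned data with its citation).

`classifyStructure()` applies the standard CSD rule: residues in
maximal runs of at least `minRun` consecutive residues with
Δδ < `helixThreshold` are helical, the rest coil.  Defaults:
`helixThreshold = -0.1` ppm (the conventional detection limit — smaller
|Δδ| is random coil) and `minRun = 4`, one helical turn, since a
"helix" shorter than a turn is not interpretable; both are parameters.
Residues without an αCH assignment stay `unassigned` and break runs.

Two caveats are inherent to the simple model.  First, the same
random-coil table is applied in every solvent; random-coil shifts are
strictly defined in water, so DMSO tables referenced to the residual
solvent peak carry a systematic offset the analysis does not correct.
In the bundled assignment fixtures this is visible directly: the *mean*
Δδ(αCH) is more negative in DMSO than in TFE/H₂O (the N-terminal αCH
protons are strongly upfield in the DMSO tables), even though the
per-residue helical pattern in TFE is the expected one — a reminder
that cross-solvent CSD comparisons need solvent-matched referencing,
which uncorrected single-reference analysis cannot deliver.  Second, no
temperature or neighbour corrections are applied to the reference
values.

## Restraint accounting

`readUpl()`/`writeUpl()` handle a CYANA-style upper-limit text format.
`restraintStats()` bins distance restraints by sequence separation —
intraresidue (|i−j| = 0), sequential (= 1), medium-range (1 < |i−j| ≤ 4),
long-range (> 4) — with the conservation invariant that the four
categories sum to the total; `noeContactSummary()` aggregates per-pair
counts for contact diagrams.  Structure calculation itself (simulated
annealing, target functions, violation statistics, ensemble RMSDs) is
out of scope: the package counts and classifies restraints, it does not
compute structures.

## Synthetic data

The generators exist so every stage is testable without any deposited
data, and they emulate exactly the statistical structure the analysis
assumes:

* `randomPeptide()`: i.i.d. residues from a configurable composition
  (uniform over the canonical 20 by default).
* `syntheticShiftTable()`: inverts the CSD rule as a generative model —
  αCH(i) = random-coil + μ(i) + N(0, σ²), with μ = −0.35 ppm inside
  planted helix segments and 0 elsewhere.  −0.35 ppm is a typical
  helical α-proton secondary shift, comfortably beyond the −0.1 ppm
  threshold; the default noise σ in the recovery experiments is
  0.03 ppm, the order of assignment/referencing scatter.  NH and βCH
  protons are filled with flat constants (8.25 / 1.85 ppm) purely so
  generated tables exercise full reader validation.
* `syntheticRestraints()`: draws restraint lists achieving prescribed
  per-category counts exactly, with feasibility checks against the
  peptide length.

Every generator takes an explicit seed, is bit-reproducible given it,
and restores the caller's RNG state.  What the generators do *not*
emulate: peak overlap, assignment ambiguity, missing assignments,
residue-dependent noise, or any coupling between sequence and structure.
A classifier that recovers planted helices from these tables is
therefore validated for its run-length logic and noise tolerance, not
for performance on real spectra.

## Problem sizes used by the test-suite

The property tests run 1000 random (sequence, single-mutation) pairs
for the incremental-update identity (agreement to 1e-9 with full
recomputation), 100 random restraint lists for category conservation,
100 random feasible category configurations for generator round-trips,
and 200 seeded replicates of the planted-helix recovery experiment
(length 20, one 8-residue segment, σ = 0.03 ppm; per-residue accuracy
must average ≥ 95%).  The design enumerator is cross-checked against an
independent brute-force recomputation for up to 3 positions × 4
alphabet residues.

## Known limitations

* Charge is integer and pH-free; peptides dominated by His or by
  terminal charges are misrepresented.
* The Boman scale's proline entry is a convention (0), not a
  measurement.
* CSD classification uses a single aqueous random-coil reference in all
  solvents (see above) and αCH protons only; no CSI-style multi-nucleus
  consensus.
* The designed candidates are ranked purely by the descriptor panel; no
  activity model, structure prediction or synthesis-feasibility check
  is implied.
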