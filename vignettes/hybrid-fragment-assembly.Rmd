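---
title: "Hybrid ant-colony / Monte-Carlo fragment assembly: models, parameters and design notes"
author: "acofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ant-colony / Monte-Carlo fragment assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acofold)
```

## The problem and the representation

`acofold` predicts a protein backbone de novo — from the amino-acid
sequence and a predicted secondary-structure string over {H, E, L} — by
fragment assembly in torsion space.  A conformation is a sequence of
per-residue torsion tuples (phi, psi, omega); Cartesian coordinates follow
deterministically by sequential chain extension (NeRF) with fixed ideal
bond lengths and angles (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; angles
111.2°, 116.2°, 121.7°).  Each side chain is a single pseudo-atom (CEN)
placed 1.53 Å along the ideal C-beta direction; whether a real centroid
should be amino-acid specific is an open choice, and the fixed C-beta
direction is the simplest convention that keeps the model testable.
Dihedrals follow the IUPAC sign convention; the undefined terminal
dihedrals (phi of residue 1, psi/omega of the last residue) are reported
as the sentinel value +180 so that round-trips are exact and assertable.

The search space is defined by fragment libraries: `F9` and `F3` hold 200
rank-ordered 9-mer and 3-mer torsion runs per residue window (the shape of
Robetta server output, which the package can read in the Rosetta fragment
text format or generate synthetically), and `F1` — merged from both —
holds the 1-mer tuples used to refine loop residues after rough assembly.
A fragment is identified everywhere by the triple
`(library, window_start, rank)`: that triple indexes the pheromone matrix
and is the currency exchanged between the two search heuristics.

## The energy model

Five composite scores (`score0`, `score1`, `score2`, `score5`, `score3`)
are fixed weighted sums of ten centroid energy terms; the weight table is
reproduced exactly, with `score0` pure excluded volume (vdw weight 0.10)
and `score3` — the final ranking score — weighting every term at 1 except
the radius of gyration at 3.  The individual terms are deliberately simple
geometric surrogates written for this package: steric repulsion inside
4 Å, CA radius of gyration, Kyte–Doolittle burial, CEN contact classes,
neighbour-density regularity, a 5–7 Å packing-shell fraction, and four
strand/helix segment-pairing terms (counts at 4.2–5.5 Å and 7–10 Å,
paired-segment count, and a 0.1 penalty per paired strand pair more than
30° from parallel/antiparallel).  They preserve each term's qualitative
role — compaction, burial, excluded volume, sheet formation — and are
cheap, deterministic and rigid-motion invariant (all property-tested).
They are *not* Rosetta's knowledge-based potentials; absolute energies are
not comparable to any published value, and no claim about real-protein
accuracy follows from them.

## The two heuristics and their coupling

**MMAS colonies.**  Each of `n_colonies` ant colonies minimises one of the
five composite scores (default assignment cycles score3, score2, score1,
score5, score0) against a *single shared* pheromone matrix bounded in
`[tau_min, tau_max]`.  An ant builds a conformation from the extended
chain (phi −120, psi 120) by `n_tries` insertions, choosing F9 with
probability `pf`, the window uniformly, and the candidate by the selection
law `tau^alpha * eta^beta` with an epsilon chance of a uniform pick.  The
heuristic desirability is
`eta = 0.5 * (SS-label match fraction) + 0.5 / (1 + rank)` — strictly
positive, maximal for a rank-0 fragment matching the predicted secondary
structure.  The iteration best is polished by a one-flip Metropolis local
search (best-visited returned, so its energy never increases) and by loop
refinement restricted to L-labelled residues with F1 proposals.  The
update batch evaporates every cell by `(1 - rho)`, deposits the
iteration-best's quality — energy rescaled linearly to [0, 1] against the
colony's running best/worst references — on every cell it used, deposits
externally supplied fragments the same way, and clamps.

**The staged Monte-Carlo predictor.**  Five stages minimise score0,
score1, score2/score5 (strictly alternating per 200-cycle block), score3
and score3 again; stages 1–4 propose fragment insertions (9-mers first,
3-mers after) with uniform window and candidate choice — the MC predictor
deliberately does not read the pheromone matrix, the exchange is
asymmetric — and stage 5 proposes single-residue wrapped-Gaussian torsion
moves (sigma 10°) and returns its best-visited conformation.  Cycle counts
are `(2000, 2000, 2000, 4000, 4000) * increase_cycles / 4` at a fixed
temperature of 2.0; the upstream protocol's internal temperature ramping
is out of scope.

**Exchange.**  Colonies publish their iteration-best conformations; at
every stage boundary the MC predictor blends its working conformation
toward the set's per-residue *circular-mean* torsions along the shortest
arc by fraction `lambda` (default 0.3; the arithmetic mean of 170° and
−170° is 0°, the circular mean 180°, which is why the mean must be
circular).  In return, every fragment the MC predictor accepts is streamed
to the colonies and deposited into the shared matrix as if chosen by a
"best-so-far ant", with quality computed from the MC conformation's stage
energy against the receiving colony's references (clipped to [0, 1]), or
0.5 when no energy is attached.  Each fragment batch is drained exactly
once, by whichever colony updates next: the matrix is shared, so a single
deposit reaches everyone, and re-depositing per colony would introduce an
8-fold multiplier nothing in the protocol calls for.

**Scheduling.**  The run modes are `sequential_mc` (decoys0), `shmo`
(colonies only, decoys3) and `mhmo` (8 colonies + 1 MC worker = 9 workers;
decoys1, decoys2, and decoys12 = the lowest-score3 union).  Workers are
*not* OS threads here: R's process model cannot share a live matrix
across processes without serialisation that would change the update
semantics, so the driver advances workers cooperatively round-robin — each
colony one iteration, the MC worker one stage — draining channels at those
boundaries.  This makes the entire run a pure function of
`(config, seed)`, which the tests assert bit-for-bit; the order-dependence
that a truly concurrent scheme would add is exactly the non-determinism
the parallel design tolerates (deposit-only batches on disjoint cells
commute; interleaved evaporation does not).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_ants` | 8 | conformations built per colony iteration |
| `alpha`, `beta` | 1, 2 | pheromone / heuristic exponents |
| `rho` | 0.1 | evaporation per update batch |
| `epsilon` | 0.05 | uniform random pick probability |
| `pf` | 0.5 | probability of proposing a 9-mer |
| `n_tries` | 2·L | insertions per ant (L = chain length) |
| `max_iter` | 50 | iteration budget (default termination) |
| `local_T` | 2.0 | Metropolis temperature (colony and MC) |
| `local_L` | L | one-flip proposals per local search |
| `tau_max`, `tau_min` | 1, `tau_max/(2·candidates)` | MMAS bounds |
| `lambda` | 0.3 | stage-boundary blend toward colony averages |
| `increase_cycles` | 4 | MC schedule multiplier |
| quotas | 800 / 100 | colony / MC decoys (full protocol) |

The printed parameter values in the upstream description of this scheme
are unreadable in the available text, so these defaults are declared, not
inferred; all are overridable through `colony_params()` and
`run_config()`, and the weight presets accept per-term overrides.

Termination follows one of four criteria — iteration budget (default),
CPU-time budget, no best-energy improvement over the last ten iterations,
or coverage of more than half the pheromone cells; coverage is bookkept
from the colony's own selections, an approximation documented in
`check_termination()`.

## Decoy statistics

The population protocol: drop the worse-scoring half of every decoy set by
score3 (800 → 400, 100 → 50), pool hybrid sets by score3
(`union_best`), and summarise accuracy as Cα-RMSD after Kabsch
superposition.  `bootstrap_percentile()` draws `folds = 50` resamples with
replacement and takes the *nearest-rank* p-quantile of each — for
p = 0.10 and n = 400 that is exactly the 40th order statistic — returning
the across-fold mean and standard deviation; `boxstats()` uses
linear-interpolation quartiles.  Two quantile conventions coexist on
purpose, each pinned where it is used.  Significance between decoy
populations is a two-sided Mann–Whitney U test at alpha = 0.05 (the
protocol calls for a significance test without naming one; the rank-sum
test makes no normality assumption about RMSD distributions).

## Synthetic data: what it emulates and what it does not

`generate_synthetic_library()` emulates the *shape* of Robetta output: 200
rank-ordered candidates per window, ideal-secondary-structure torsions
(helix −57/−47, strand −120/120, loops a uniform mixture over the basins
(−75, 150), (−60, −30), (60, 30)) plus wrapped Gaussian noise, candidate 0
noise-free, omega trans.  It does not emulate profile-based fragment
picking, homolog filtering, or the torsion correlations of real fragments.

`make_toy()` builds instances small enough to enumerate: the reachable
assembly space is the breadth-first closure of the insertion moves from
the extended chain (overlapping windows make the reachable set
order-dependent, so a per-window product is the wrong enumeration), capped
at 10⁴ states, with the exact optimum stored.  Oracle-equivalence tests
use loop-free toys so the downhill-only search and the enumeration cover
the identical move space.

`make_benchmark_like_target()` plants a known native: secondary-structure
elements keep ideal torsions, each interior loop's torsions are optimised
(Nelder-Mead on score3 of a poly-alanine chain, three basin starts) for a
compact clash-free arrangement, hydrophobic residues are assigned to the
fold's buried positions — inside a helix this reproduces the ~3.6-residue
amphipathic period — and candidate 0 of every window carries the native
torsions.  The optimisation step is essential fixture design, not
cosmetics: with straight ideal elements the "native" is *not* an energy
basin (a bent compact helix beats a straight one under the rg-weighted
score3), and a search-quality comparison against random assembly would
measure nothing.  With the planted basin, a hybrid run at small quotas
beats a random-assembly baseline of matched sample count in Cα-RMSD in
9–10 of 10 paired seeds.  Passing these tests shows that the machinery
searches the landscape it is given and that the exchange channels work;
it shows nothing about accuracy on real proteins with real fragment
libraries and real energies.

## Numerical choices and degenerate inputs

Angles live on [−180, 180) in degrees; the sentinel +180 marks undefined
terminal dihedrals.  F1 deduplication is exact at 1e-6° (the upstream
similarity measure is not legible; exact matching is the conservative
choice).  Collinear atoms make dihedrals an error, not an NA.  Kabsch uses
SVD with the determinant correction, so reflections are never returned.
Quality rescaling returns 1 on a degenerate reference interval.  The
one-flip search returns the best conformation visited rather than the
last, making its non-worsening contract assertable.  Problem sizes in the
test-suite and acceptance script (3-residue toys, 30-residue planted
folds, 30-candidate libraries, quotas of a few decoys) are chosen so every
stochastic check re-runs in seconds while the full-protocol counts
(800/100 decoys, 200 candidates per window, 9 workers) are still exercised
where they are cheap.

## Known limitations

Fixed ideal bond geometry (no bond/angle variation, trans-omega unless a
fragment says otherwise); surrogate energies with no claim of
bit-compatibility with any published potential; cooperative scheduling
rather than true concurrency; no decoy clustering or near-native selection
(out of scope upstream too); loop refinement only at L-labelled residues;
the coverage termination criterion is an approximation from selection
bookkeeping.
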