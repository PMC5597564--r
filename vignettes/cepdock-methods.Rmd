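---
title: "cepdock: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cepdock: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cepdock is a small protein–ligand docking engine built to study one search
algorithm: a real-coded genetic algorithm with a *crossover elitist
preservation* (CEP) mechanism and Lamarckian local search (CEPGA).  This
vignette is the package's own account of the models it implements, the
parameters that matter, and the places where the design was genuinely open.

## The pose model

A ligand pose is a real vector of length $7 + T$:

* genes 1–3 — rigid-body translation in Å;
* genes 4–7 — a unit quaternion $(w, x, y, z)$ rotating the ligand about the
  centroid of its rigid ROOT block;
* genes 8…$7+T$ — one dihedral angle per rotatable bond, in radians,
  wrapped to $(-\pi, \pi]$.

The decoder applies torsions depth-first from the ROOT outward in PDBQT
record order (each rotation is about the current position of its bond axis),
then the whole-body rotation, then the translation.  The pivot — the
ROOT-block centroid — is an arbitrary but fixed convention; any fixed pivot
yields the same search space, it only relabels translations.  Quaternions
are renormalized after every variation operator with tolerance $10^{-9}$;
bond lengths and all angles that do not span a rotatable bond are preserved
to machine precision, which the test suite asserts on random genomes.

RMSD between a docked pose and the reference is computed in the receptor
frame (no superposition), over heavy atoms only, without symmetry
correction.  A docking is *valid* iff RMSD $< 2.0$ Å, strictly: a pose at
exactly 2.0 Å counts as invalid.  The in-frame heavy-atom convention is the
one used throughout the docking literature for redocking experiments;
automorphism-aware RMSD is out of scope.

## The scoring function

The objective is a semi-empirical pairwise energy in the AutoDock4 style,
evaluated by direct summation over receptor–ligand atom pairs plus the
torsion-variable intraligand pairs (atoms three or more bonds apart whose
distance can change with the torsions):

$$
E = W_\mathrm{vdw}\sum \left(\frac{A_{ij}}{r^{12}} - \frac{B_{ij}}{r^{6}}\right)
  + W_\mathrm{hb}\sum \left(\frac{C_{ij}}{r^{12}} - \frac{D_{ij}}{r^{10}}\right)
  + W_\mathrm{elec}\sum \frac{332.06\, q_i q_j}{\varepsilon(r)\, r}
  + W_\mathrm{ds}\sum (S_i V_j + S_j V_i)\, e^{-r^2/2\sigma^2}
  + W_\mathrm{tor} \cdot \mathrm{TORSDOF}
$$

with $A_{ij} = \varepsilon_{ij} R_{ij}^{12}$, $B_{ij} = 2\varepsilon_{ij}
R_{ij}^{6}$ from Lorentz–Berthelot mixing of the per-type table shipped in
`inst/extdata/ad4_atom_params.tsv`, 12–10 hydrogen-bond parameters taken
from the acceptor's row whenever a donor hydrogen (HD) pairs with an
acceptor (OA, NA, SA), the Mehler–Solmajer sigmoidal distance-dependent
dielectric $\varepsilon(r)$, and $S_i = \mathrm{solpar}_i + 0.01097\,|q_i|$,
$\sigma = 3.5$ Å.  The published AutoDock4 free-energy weights
(0.1662, 0.1209, 0.1406, 0.1322, 0.2983) are the defaults.  This is a
*face-valid functional form*, not a bit-exact AutoDock reproduction: there
are no grid maps, no trilinear interpolation, and no directional
attenuation of hydrogen bonds.  Consequently absolute energies of real
complexes are not comparable with AutoDock output, and the benchmark tables
of the original docking literature are not reproduction targets here.

Numerical guards: pairs beyond the 8 Å cutoff contribute exactly zero;
distances below 0.5 Å are evaluated at 0.5 Å plus a linear penalty of
100 kcal/mol per Å of overlap, so the surface is finite and monotone into
the overlap region — no pose inside the search box can produce NaN or Inf.

Three implementations of the same definition coexist: a compiled inner loop
(`src/fastpath.cpp`) used by search contexts, a vectorized R scorer
(`scorePose`), and a naive double-loop reference (`scorePoseNaive`) that
re-derives every mixing rule per pair.  The suite asserts mutual agreement
to $10^{-9}$ on random 50-atom systems; the compiled and R routes must and
do produce identical search behavior.

## The search

One CEPGA generation, starting from an evaluated population of size $P$:

1. **Breeding** — $P$ children from rank-selected pairs (linear ranking,
   pressure $s = 1.5$: $p_i = (s - (2s-2)\,\mathrm{rank}_i/(P-1))/P$),
   one-point crossover at a uniform gene boundary with probability 0.8;
   each child records which two individuals produced it.
2. **Evaluation** of the children.
3. **CEP** — the $\lceil\theta P\rceil$ lowest-energy children are the
   elitist individuals; the parents that produced them are re-injected into
   the population, replacing $2\lceil\theta P\rceil$ distinct uniformly
   chosen non-elite members.  Elites are never replaced, and the population
   size is conserved.  Feasibility ($3\lceil\theta P\rceil \le P$) is
   checked at configuration time.  $\theta$ is restricted to $[0.01, 0.1]$;
   the default 0.05 is the midpoint.  In generation 0 individuals have no
   parents and preserve themselves.
4. **Mutation** of all non-elite members: each gene independently with
   probability `mutationRate`; translations get Gaussian noise clamped to
   the search box, torsions Gaussian noise then wrapping, and the
   orientation block is treated as one unit composed with a random rotation.
5. **Local search** — Solis–Wets refinement of the best
   $\lceil 0.06 P\rceil$ individuals: propose a Gaussian step of scale
   $\rho$, accept strict improvements, try the opposite step otherwise,
   double $\rho$ after 4 consecutive successes, halve after 4 failures,
   stop at `lsMaxIter` iterations or $\rho < 0.01$.  Improvements are
   written back into the genome (Lamarckian).

The plain-GA baseline is the identical loop with steps 3 and 5 disabled, so
paired runs isolate the CEP contribution.  A single seeded RNG drives all
operators in a documented order; identical configuration and seed give
bitwise-identical traces.  Termination is at `maxGenerations` or
`maxEvaluations`, whichever comes first; the evaluation counter increments
exactly once per objective call, cached energies are reused without
counting, and the best-ever individual with its improvement trace
(strictly decreasing energy vs. strictly increasing evaluation count) is
returned.

**Why the aggressive mutation defaults?**  The shipped defaults are
`mutationRate = 0.5` with rotational/torsional scales of ~$\pi$ —
effectively resampling the hit gene blocks — rather than the gentle rates
classic GAs use.  Docking landscapes under a pairwise potential are
funnel-plus-golf-course: outside the pocket's 8 Å attraction zone the
surface is flat, and gentle mutation lets the whole population coast into
the first touched side basin and stay there (we observed identical final
poses at 25k and 150k evaluations).  CEP is exactly the license for
aggression: the elites and their parents are shielded from loss, so the
rest of the population can afford near-restart exploration kicks while the
elite lineage exploits.  This coupling — strong elitist preservation
enabling strong exploration — is the practical content of the CEP
mechanism as implemented here.

Budgets: the full protocol is population 50, 27,000 generations, and
$1.5\times 10^6$ evaluations per docking.  The desk-scale protocol used by
the tests and benchmarks (`reducedSearchConfig()`) is population 50, 500
generations, 150,000 evaluations (the evaluation cost of 500 generations
under the default local-search schedule), local search capped at 50
iterations; the planted-pose regression runs at 100,000 evaluations per
run so that thirty runs finish in a few minutes on one CPU.

## Synthetic fixtures: what they emulate, and what they do not

Real crystal complexes cannot provide ground truth for a search algorithm
at desk scale, so the generator (`makeFixture`) builds systems where the
answer is planted:

* a branched heavy-atom ligand — a small ring of alternating C/N plus a
  tetrahedral zig-zag chain carrying $T \in [0, 15]$ rotatable bonds, with
  hydrogen-bond acceptors every `acceptorEvery` chain positions;
* a *planted genome* drawn from the fixture seed (near-extended torsions,
  resampled until internally clash-free) whose decoded coordinates are the
  reference pose;
* a pocket built as a **molded complementary surface**: a wall oriented
  along the ligand's flattest principal plane is tiled with receptor atoms
  on a `gridSpacing` lateral grid, each lowered to the highest position
  outside the van der Waals contact envelope of the planted pose, so the
  surface hugs the ligand without clashing and leaves an open approach
  face.  Each surface atom takes the opposite partial charge of its
  nearest ligand atom, and the atom directly beneath each acceptor becomes
  a donor hydrogen at the 12–10 equilibrium distance (kept only if its net
  contribution is strongly attractive).  Ligand charges alternate in sign
  with seeded irregular magnitudes and a strongly charged head atom, so no
  shifted or flipped registry ties the planted pose.

Earlier designs placed one isolated partner atom per ligand atom, as a
naive reading of "complementary pocket" suggests; they fail in instructive
ways (isolated shells surround the ligand like a cage no approach path can
thread; hydrogen-bond-only wells are too narrow to act as a funnel; dense
acceptor chains let decoy poses chelate two donors with one acceptor and
beat the planted contact map).  The molded surface is what makes the
planted pose simultaneously *deep*, *global*, and *reachable*.

A fixture self-test (`checkFixture`) verifies by Monte Carlo that the
planted pose scores below the minimum of a random-pose sample.  The
recoverability regression — CEPGA finds RMSD < 2 Å in at least 8 of 10
seeded runs for $T \le 4$ — was calibrated once during development and then
frozen: the benchmark instances are `fixtureSpec(nTorsions = T,
acceptorEvery = 2)` with fixture seeds 3, 7, 3 for $T = 0, 2, 4$, playing
the role the crystal complexes play in a real benchmark (specific, fixed
problem instances of graded difficulty).

What passing these tests shows: the search machinery optimizes a rugged
13–11-dimensional pose landscape to its known global basin, reliably and
reproducibly.  What it does not show: performance on real receptors, whose
pockets are three-dimensional, partially flexible, solvated, and scored by
grid-interpolated force fields; the fixtures have no hydrogens, no ring
conformers, no realistic valence chemistry.

The analytic landscapes (`makeLandscape`) serve the algorithm-level tests:
a quadratic bowl (exact optimum), a Rastrigin-style multimodal surface
(global minimum $-1$ at the origin among many local minima), and its
lattice discretization (11 points per dimension on $[-5, 5]$, $11^3$ states
for three genes) whose global minimum an exhaustive oracle recovers by
enumeration — the search can then be required to match, and never beat,
the oracle.

## Benchmark harness and statistics

`runExperiment` mirrors the ten-independent-runs protocol: per (instance,
algorithm) cell it runs seeds `baseSeed + 1 … baseSeed + R`, records every
trace, and aggregates lowest energy, smallest RMSD, and the success count
under the strict 2 Å rule; a crashed run becomes a failed cell, not a
failed experiment.  `boxStats` uses Tukey conventions (type-7 quartiles,
whiskers at the most extreme values within 1.5 IQR).  `pairwiseTest` is a
one-sided Wilcoxon–Mann–Whitney test of "algorithm A yields lower energies
than B": exact enumeration of the rank-sum distribution for at most 10
tie-free observations per arm (so maximally separated 3-vs-3 samples give
exactly $1/\binom{6}{3} = 0.05$), normal approximation with tie correction
and no continuity correction otherwise.  Under the exact distribution the
two opposite one-sided p-values sum to $1 + P(W = w_\mathrm{obs})$ — the
discrete mass at the observed statistic — while under the continuous
approximation they sum to exactly 1, which is the mirrored off-diagonal
structure such comparison tables show.  All-tied samples report $p = 0.5$
with a tie flag.  The choice of a rank test over a t-test is an
interpretation: run-energy distributions of stochastic optimizers are
skewed and occasionally heavy-tailed, and the mirrored p-value structure
is characteristic of one-sided two-sample rank tests.

## Degenerate inputs and tie-breaks

* Population size below 2 is rejected (crossover needs two parents);
  genome length 1 skips crossover cuts (copies returned).
* Elite identification breaks ties by stable sort order (first occurrence
  wins); duplicate elites sharing parents insert their parents once per
  record, and duplicates are permitted in the population.
* `maxGenerations = 0` returns the best of the random initial population,
  consuming exactly $P$ evaluations.
* Local search with `maxIter = 0` is a no-op consuming zero evaluations;
  budget exhaustion mid-search returns the best point so far.
* An empty receptor scores as torsional penalty plus intraligand terms.
* Water residues (HOH/WAT) are dropped on receptor input with a message;
  unknown atom type codes and shifted fixed-width columns are hard errors
  naming the offending lines.

## Known limitations

* The scoring function is AutoDock4-*styled*, not AutoDock4: energies are
  not comparable with published grid-map results, which is why external
  benchmark energies are out of scope as numeric targets.
* Bonds are inferred from distances on PDBQT input (the format carries no
  bond records); exotic bond lengths would need explicit topologies.
* The pose PDBQT writer emits coordinates at the format's 3-decimal
  precision; the full-precision genome travels in a `REMARK GENOME` line,
  which is what result round-trips should re-score from.
* Receptor flexibility, ring-conformer sampling, symmetry-corrected RMSD,
  and swarm/bee-colony comparator algorithms are out of scope.
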