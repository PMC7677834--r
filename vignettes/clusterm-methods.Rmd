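---
title: "Detecting conserved protein complexes across PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved protein complexes across PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterm)
```

## The problem

A protein complex is a group of proteins that assemble into a molecular
machine. In a protein–protein interaction (PPI) network a complex shows up as
a set of proteins that interact densely with one another while having few
interactions with the rest of the network, i.e. it is *topologically
separable*. A *conserved* complex additionally has orthologous counterparts
— proteins with high sequence similarity — in the networks of other species,
and the orthology is often many-to-many rather than a clean one-to-one map.

`clusterm` detects such conserved complexes across k ≥ 2 PPI networks by a
divide-and-conquer strategy: rather than aligning whole networks, it starts
from cross-species seed tuples ("protein spines"), carves out a small,
well-separated subnetwork around each seed protein in each network, and then
prunes the union of those subnetworks to a complex that is both dense within
each species and homology-rich across species. Because every step works on a
neighborhood of a few dozen proteins, the cost scales with neighborhood
size, not network size, and the per-spine computations are independent and
trivially parallel.

## Step 1: spines

A spine is a tuple \((v_1, \dots, v_k)\), one protein per network, believed
to be mutually homologous. Spines are normally produced by a multiple
network aligner and loaded with `read_spines()`; the file format (k-column
TSV) matches what such tools emit. For self-contained use,
`build_spines()` derives spines from the similarity map itself by
deterministic greedy chaining of reciprocal best hits: proteins of network 1
are visited in lexicographic order and chained through networks 2..k,
taking at each hop the highest-similarity partner not yet consumed and
requiring it to be a reciprocal best hit. The builder is deliberately
one-to-one — many-to-many orthology re-enters later through the cost
function, which may recruit any similar protein into a complex, so the
restriction only affects seeding.

## Step 2: minimum-conductance sets

Separability is measured by conductance. For a set \(S\) in a network with
degrees \(d_i\),

\[
\phi(S) = \frac{|E(S,\bar S)|}{\mathrm{vol}(S)},\qquad
\mathrm{vol}(S)=\sum_{i\in S} d_i,
\]

the fraction of the interactions touching \(S\) that leave it. This is the
small-set simplification of the usual definition with
\(\min\{\mathrm{vol}(S),\mathrm{vol}(\bar S)\}\) in the denominator, valid
because candidate complexes are tiny relative to the network
(`conductance(strict = TRUE)` gives the unsimplified value).

For each spine protein, the local neighborhood \(H\) is the seed plus the
\(m-1\) best-ranked proteins of an approximate personalized PageRank vector
(`personalized_pagerank()`, local push with residual below
`tolerance` × degree at every node, so work is proportional to the visited
neighborhood). The refined set is then the *exact* optimum of the binary
fractional program

\[
\min_{x \in \{0,1\}^H,\ x_{seed}=1}
\frac{x^\top (D - A^H)\, x}{x^\top D\, x},
\]

where \(A^H\) is the adjacency of the subnetwork induced by \(H\) and \(D\)
carries the members' **full-network** degrees. With that convention the
numerator is exactly the number of edges leaving the selection into the rest
of the network, so the program minimizes true network conductance over
seed-containing subsets of \(H\). This degree convention is a deliberate
design choice: if \(D\) were taken from the induced subnetwork instead, any
union of connected components of \(H\) — in particular all of \(H\) — would
have numerator 0 and the optimization would be vacuous. The induced-degree
variant is still available (`degrees = "induced"`) for completeness.

Exactness matters here: heuristic local clustering can leave weakly attached
satellites in the set, and the later pruning step has no topological
separability term to remove them. Two solver modes are provided:

* `"exact"` (default; `"mip"` is accepted as an alias): Dinkelbach's
  parametric method for fractional programming. At parameter
  \(\lambda = p/q\) the subproblem \(\min_S q\,\mathrm{cut}(S) -
  p\,\mathrm{vol}(S)\) is a quadratic pseudo-Boolean minimization whose
  pairwise terms are all attractive, hence submodular, and it is solved
  exactly as an s-t minimum cut (via `igraph`'s max-flow) with the seed
  clamped to the source. All cut/volume arithmetic is integer, so the
  iteration terminates at the exact optimum, typically in 2–4 cuts.
* `"exhaustive"`: vectorized enumeration of all \(2^{|H|-1}\)
  seed-containing subsets (limited to \(|H| \le 24\)). This is the
  independent oracle; the test suite checks that both modes return the same
  minimal conductance on randomized neighborhoods.

If the parametric iteration ever failed to converge (it has a hard
iteration cap), the code falls back to exhaustive enumeration for small
neighborhoods and otherwise to the best sweep cut over PageRank order, with
a warning.

Ties in the exhaustive mode are broken toward the larger subset, then the
lexicographically smallest member list; the parametric mode may return a
different optimizer only among exact ties, which is why the pipeline's
determinism contract is stated per solver mode.

Degenerate cases: an isolated seed (degree 0) keeps unit PageRank mass and
yields the singleton set with conductance 1 by the zero-volume convention; a
selection with zero volume is likewise scored 1 (worst).

## Step 3: pruning to a conserved complex

The per-network refined sets \(\hat H_1, \dots, \hat H_k\) are pooled, and a
binary indicator \(\delta_a\) per protein is optimized against

\[
F = -\left(
\sum_{j=1}^{k}
\frac{\sum_{a,b \in \hat H_j} A^{(j)}(a,b)\,\delta_a \delta_b}
     {\sum_{c \in \hat H_j} \delta_c}
+ \lambda\,
\frac{\sum_{j \ne l} \sum_{a \in \hat H_j, b \in \hat H_l} s(a,b)\,\delta_a \delta_b}
     {\sum_{j}\sum_{c \in \hat H_j} \delta_c}
\right).
\]

The first term sums each network's interaction density; the second is the
total cross-network similarity per selected protein; \(\lambda\) balances
the two. Both inner sums run over ordered pairs — the natural reading of the
matrix notation — so a triangle contributes density 2 (= 2·3 edges / 3
proteins) and each unordered homology pair counts twice. The convention is
stated explicitly because it scales the density term by 2 relative to the
unordered reading and therefore interacts with \(\lambda\).

`greedy_prune()` starts with everything selected and repeatedly removes the
single protein whose removal lowers \(F\) most (steepest descent; ties go to
the lowest network index, then protein ID), stopping when no removal
strictly lowers \(F\). With cached incremental updates each candidate
removal is O(1), giving the O((km)²) bound per spine. Similarity scores
\(s(p,q) \in [0,1]\) come from BLAST bit scores normalized by the geometric
mean of the self-alignment scores (`normalize_bitscores()`), thresholded at
0.1.

Post-processing (`postprocess()`) removes exact duplicates (all k sets
equal; first spine wins), drops complexes whose summed internal similarity
is below β = 0.1, and finally drops complexes with fewer than 3 proteins in
any species — the same filter the evaluation protocol applies.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 20 | PageRank neighborhood size per spine protein. Chosen to comfortably contain a complex (typical complexes have 3–15 subunits) while keeping the exact solver's instances small. |
| `restart` | 0.15 | PageRank restart probability, the standard walk-with-restart value. |
| `tolerance` | 1e-4 | push residual per unit degree; at `m` = 20 the induced ranking is stable well below this. |
| `lambda` | 10 | homology weight; the natural sweep is {1, 10, 100} and 10 is the middle value. `grid_sample()` supports tuning under an evaluation budget. |
| `beta` | 0.1 | minimum summed internal similarity of a reported complex. |
| `min_size_per_species` | 3 | minimum per-species complex size. |
| `exhaustive_cap` | 15 | largest neighborhood enumerated when falling back from the parametric solver. |

## Evaluation metrics

For two species, a reference pair \(A = (A_1, A_2)\) is compared against a
prediction \(B = (B_1, B_2)\) with the neighborhood affinity
\(w(X,Y) = |X\cap Y|^2 / (|X||Y|)\):

* **fraction**: share of references with some prediction achieving
  \(w \ge 0.25\) in *both* species;
* **Sn / PPV / Acc**: complex-wise sensitivity and positive predictive
  value over per-species overlap counts, and their geometric mean, with
  proteins namespaced by species so cross-species unions are disjoint;
* **MMRC**: maximum-weight one-to-one matching between references and
  predictions, edge weights the harmonic mean of the two per-species
  affinities (0 when both are 0), edges below 0.25 dropped, total matched
  weight divided by the number of references;
* **composite** = fraction + Acc + MMRC ∈ [0, 3].

GO-based measures work for any k: `high_level_terms()` keeps terms with
information content \(-\log(|g|/|root|) > 2\) (natural log, the common IC
convention; the base is switchable and cancels inside NE) after removing
IEA/IPI/ISS-evidenced annotations — those would leak the algorithm's own
inputs (interactions, sequence similarity) into the evaluation.
`mne()` computes the mean normalized entropy of term assignments per
complex, with \(p_j\) read as the fraction of protein–term *assignments*
on term \(j\) (proteins carrying several terms contribute to each);
`coverage()` counts distinct proteins in qualifying complexes (union over
complexes — the reading of "proteins covered by the output"; a
multiplicity-counting switch is provided).

## Robustness harness

`rewire_network()` injects topological noise by degree-preserving double
edge swaps — the standard rewiring null model — until the requested
fraction of original edges is displaced; `perturb_homology()` applies the
same swaps to the similarity bipartite graph, each swapped pair inheriting
the score of the original pair with the same left endpoint (the choice is
arbitrary but consistent; any such rule preserves the perturbation
semantics). No connectivity constraint is imposed on swaps.
`replicate_and_average()` runs the pipeline over the four conditions
(clean, topology-only, homology-only, both), averages the metric reports
over replicates, and summarizes the per-condition composite scores.

## The synthetic benchmark

`generate_planted_world()` builds k networks that contain the features the
method exploits: `n_complexes` dense planted modules (within-module edge
probability `p_in`, disjoint within a network, resampled until connected —
a complex is a connected assembly, and an internally disconnected "module"
would be unrecoverable by any local method), attached to a background
Erdős–Rényi graph with per-pair probability `p_out`, plus index-matched
ortholog similarities across counterpart modules (clipped
Normal(0.6, 0.15)) and uniformly sprinkled decoy similarities.

The defaults — two networks, ten complexes of five proteins, `p_in` = 0.9,
`p_out` = 0.02, 200 background proteins with mean degree ≈ 4 — are the
package's benchmark conditions: module densities and background sparsity in
the range reported for curated complexes and PPI networks, and decoy rate
0.001 of possible cross pairs so that spurious homology exists but does not
dominate. What the generator does **not** emulate: scale-free degree
distributions, overlapping complexes, and species-asymmetric complex sizes.
Passing the recovery tests therefore demonstrates correctness of the
machinery on separable planted structure, not performance on real
interactomes.

At these conditions the test suite checks (fixed seeds, 10 worlds each):
perfect recovery (composite exactly 3) when `p_out` = 0 with no decoys;
mean matched fraction ≥ 0.8 and mean MMRC ≥ 0.7 at `p_out` = 0.02;
monotone decay of the matched fraction as `p_out` grows through 0.05 and
0.1; and a composite drop below 0.5 under simultaneous 10% rewiring of
edges and homology pairs (10 replicates). Problem sizes (≈ 225 proteins per
network, 10 spines) keep a full pipeline run below a second so the whole
protocol stays desk-scale.

## Numerical and design notes

* All graph containers, max-flow, matching and random-graph generation are
  `igraph`; the package's own code is the algorithmics: push PageRank, the
  parametric conductance solver, the cost function and pruning, the
  rewiring and the metrics.
* Conductance comparisons in the exhaustive solver use a 1e-12 absolute
  tolerance only to group floating ties; the parametric solver's
  termination test is exact integer arithmetic.
* The greedy prune accepts a removal only if it lowers the cost by more
  than 1e-12, so cost traces are strictly decreasing and termination is
  guaranteed.
* `run_clusterm()` output is canonically sorted by complex signature, which
  together with per-spine independence makes results identical for any
  worker count and spine order.
* Maximum-weight bipartite matching in `mmrc()` is delegated to igraph; the
  tests cross-check it against brute-force assignment enumeration on all
  instances up to 7×7.
* The greedy prune is a heuristic: on small random candidates it attains
  the exhaustive optimum of the cost in most but not all cases (the suite
  asserts ≥ 70% exact hits and that greedy never beats the oracle).

## Known limitations

* The pairwise evaluation metrics are defined for k = 2; for k > 2 only
  MNE and coverage apply, plus pairwise projections of planted truth.
* Similarity input assumes symmetric normalized scores; asymmetric
  homology evidence must be collapsed beforehand (the BLAST reader keeps
  the maximum bit score per pair).
* Edge-list files cannot express isolated proteins, so isolates are lost on
  a write/read round trip of generated worlds.
* No confidence weighting of interactions: networks are unweighted simple
  graphs, matching the usual public PPI snapshots.
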