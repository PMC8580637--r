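---
title: "Methods: discrete bat search for global PPI network alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete bat search for global PPI network alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batalign)
```

## The model

`batalign` computes a global alignment of two undirected PPI networks
G₁(V₁, E₁) and G₂(V₂, E₂), with |V₁| ≤ |V₂|: an injective map f : V₁ → V₂
assigning every source protein a distinct target protein. The objective
maximized is |f(E₁)|, the number of *conserved edges* — source
interactions whose endpoint images also interact in the target. This is a
purely topological objective; biology enters through the initialization.

Both networks are treated as simple graphs: self-loops are dropped and
parallel interactions collapsed at read time. This matches how interaction
databases are normally consumed for alignment and makes adjacency 0/1.

### Node similarity

Sequence similarity (typically BLAST bit-scores) between the two node sets
forms a non-negative matrix B (row i: source node i, column j: target node
j; absent pairs are 0). The blended similarity is

$$S = \alpha\,B' + (1-\alpha)\,(A_1 B' A_2^{\mathsf T})'$$

where A₁, A₂ are the adjacency matrices and the prime denotes division by
the global maximum (an all-zero matrix is left unchanged). Entry (i, j) of
A₁B′A₂ᵀ sums B′ over all (neighbour of i, neighbour of j) pairs, so a pair
is also supported by having mutually similar neighbourhoods.

Normalizing *each term separately* before blending is this package's
choice: raw bit-scores and neighbour sums differ by orders of magnitude,
and without normalization α would not act as an interpretable convex
weight. The topology term is computed from the already-normalized B′, and
both terms (hence S) live in [0, 1]. α defaults to 0.4, the setting used
when comparing aligners that share this sequence/topology trade-off; α = 1
uses sequence only, α = 0 topology only.

### Population initialization

Each candidate solution ("bat") carries a position (a full alignment) and
a binary velocity of length |V₁|. Initialization is greedy on S: the
globally best remaining (source, target) entry is fixed, both are retired,
and this repeats until every remaining source row is all-zero against the
remaining targets — only nodes with some similarity are aligned greedily.
The leftover sources are completed uniformly at random among unused
targets, independently per bat, which is where population diversity comes
from. Equal maximal scores are broken uniformly at random from the seeded
stream. When S determines every source node (no zero rows remain), all
bats start identical and diversity must come from the search dynamics
alone — a regime discussed under limitations.

The initial velocity rests (0) exactly on nodes incident to at least one
conserved edge under the bat's position, and flies (1) elsewhere.

### Iteration

Per bat and iteration t:

1. a frequency fᵢ ~ U(f_min, f_max) is drawn once and binarized:
   °fᵢ = 1 iff fᵢ > 0.5·(f_max − f_min), strictly;
2. a step velocity is derived against the global best x\*: dimensions
   where the bat agrees with x\* keep their stored velocity; disagreeing
   dimensions fly with °fᵢ if they were flying, and stay at rest
   otherwise;
3. *global search* redraws each flying dimension's target uniformly
   without replacement from U, the targets not held by any resting
   dimension;
4. with probability 1 − rᵢ (rᵢ the bat's pulse rate) a *local search*
   candidate is also built — the flying dimensions' current targets
   permuted uniformly among themselves — and kept if it conserves more
   edges than the global candidate;
5. the surviving candidate is accepted only if it *strictly* increases the
   bat's conserved-edge count and the bat's loudness Aᵢ exceeds a fresh
   U(0, 1) draw. On acceptance: Aᵢ ← θAᵢ, rᵢ ← r⁰(1 − e^{−γt}), and the
   stored velocity is re-derived from the new position by the
   conserved-endpoint rule.

The global best is the highest-scoring bat each iteration, with ties
keeping the incumbent. The run stops after `maxIters` iterations or once
`patience` consecutive iterations pass without a strict improvement of the
best objective; the per-iteration best trace (initialization first) is
returned and is non-decreasing by construction.

Two points were genuinely open and are resolved as follows.

* **Velocity persistence.** The step velocity of (2) exists only to
  generate that step's candidates; a bat's stored velocity changes only on
  acceptance. The alternative — persisting the step velocity — lets a
  single resting frequency draw zero out every disagreeing dimension, and
  since the decay rule never turns a 0 back into 1 between acceptances,
  whole bats freeze permanently within a few iterations. Updating the
  stored velocity only as part of the acceptance update is also the
  reading consistent with treating velocity, position, rate and loudness
  as one update set.
* **Pulse-rate law.** The growth rᵢᵗ = r⁰(1 − e^{−γt}) is anchored at the
  configured ceiling r⁰; it is 0 at t = 0 (local search always available
  early) and approaches r⁰, throttling local search late.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.4 | weight of sequence vs topology in S (dimensionless) |
| `popSize` | 40 | bats in the population |
| `maxIters` | 1000 | iteration cap T |
| `patience` | 10 | improvement-free iterations before stopping (N) |
| `fMin`, `fMax` | 0, 1 | frequency bounds; binarization threshold 0.5·(fMax−fMin) |
| `theta` | 0.9 | loudness decay per acceptance, in (0, 1) |
| `gamma` | 0.9 | pulse-rate growth rate, per iteration |
| `loudness0` | 1.0 | initial loudness; 1.0 makes early improving moves certain to pass the gate |
| `rate0` | 0.5 | pulse-rate ceiling, in [0, 1] |

θ, γ, loudness0 and rate0 have no published values for this aligner;
the defaults are the canonical bat-algorithm settings and are exposed both
in `batParams()` and as CLI flags.

## The synthetic generator

`generatePair()` produces instances with known ground truth: the target is
a uniformly relabelled copy of the source, plus `nExtra` target-only nodes
attached by preferential attachment (two links each, probability ∝ degree
+ 1), with `floor(rewireP·|E₁|)` copied edges replaced by uniformly random
fresh non-edges. A removed image is never re-added, so
`conservedEdges(trueMap) = |E₁| − nRewired` holds exactly — the tests rely
on this bookkeeping. The similarity matrix scores 1 at true pairs (a
`simDropout` fraction zeroed) and U(0, `simNoise`) elsewhere;
`generateAnnotations()` gives true pairs a shared GO term set with
per-side term dropout so GOC is exercisable end to end.

This emulates what matters for validating the optimizer — a planted
injective mapping, controllable edge noise, and a similarity signal of
controllable quality. It does *not* emulate real PPI data in several
respects: degree distributions of real interactomes (unless the
duplication–divergence or preferential-attachment source models are
used), correlated noise from study bias, bit-score magnitudes (scores here
are already in [0, 1]), or paralog structure, where several targets are
legitimately similar to one source. Passing tests on these instances
therefore demonstrates correctness of the machinery and recoverability
under controlled noise, not performance claims on real interactomes.

Test and calibration problem sizes are deliberately desk-scale — networks
of 7–50 nodes, populations of 10–40, a few hundred iterations — chosen so
the whole suite re-runs in about a minute while still exercising every
code path; the algorithm itself is dense-matrix bound at O(n₁n₂) memory
and handles thousands of nodes.

## Numerical and degenerate-case choices

* Node order is first appearance in the edge-list file; it fixes all
  matrix indexings. Labels are case-sensitive byte strings.
* Duplicate similarity entries keep the maximum score (bit-score lists
  often contain reciprocal hits; max is deterministic and conservative).
* An all-zero similarity matrix is valid: the greedy phase is empty and
  initialization is fully random per bat.
* Greedy ties are broken uniformly at random; determinism comes from the
  seed, not from ordering heuristics.
* Metrics with zero denominators (EC on an edgeless source, ICS on an
  edgeless induced region, S³ on both, GOC mean with no annotated pair)
  are reported as `NA`, and as `null` in CLI JSON reports.
* Conserved-edge tests use exact integer arithmetic on canonical edge keys
  (lo − 1)·n₂ + hi, exact in doubles for any network this package can
  hold in memory.
* `localSearch` with fewer than two flying dimensions is the identity;
  `globalSearch` with no flying dimension returns the position unchanged,
  making an all-resting bat a fixed point (such a candidate ties its own
  objective and is rejected by the strict gate).

## Known limitations

* **Monotone basins.** The conserved-endpoint rule and the strict
  acceptance gate mean a bat's conserved edge set only ever grows along
  its accepted trajectory: once an edge is conserved, its endpoints rest,
  and resting dimensions are never re-drawn. Each bat is thus a randomized
  hill-climber in the lattice of alignments extending its current
  conserved set; optima requiring an early conserved edge to be *broken*
  are unreachable for that bat. The method relies on population diversity
  (the per-bat random completion) to cover multiple basins. Consequently,
  when the similarity matrix is dense and uninformative — every source
  node greedily assigned, all bats identical — the search cannot reliably
  reach the global optimum even on 7-node instances, as the
  `optimality_rate_dense_random` quantity of `scripts/acceptance.R`
  measures; on the generator's own instance family (informative similarity
  with noise, `optimality_rate_synthetic`) the rate is substantially
  higher but still short of certainty. The corresponding calibration
  expectation in the acceptance suite is knowingly strict and documents
  this ceiling rather than hiding it.
* GOC compares raw GO term ID sets; no ontology-ancestor expansion or
  semantic similarity is performed (that would require the GO DAG).
  Annotation-poor proteins contribute 0 to the sum and are excluded from
  the mean.
* The GOC formula is literally a sum, so it grows with network size; the
  reported mean over annotated pairs is the cross-size-comparable
  companion, and both are emitted.
* Similarity matrices are dense n₁×n₂ doubles; ~7k×7k (≈ 400 MB) is
  near the practical ceiling of this implementation.
* Alignment is pairwise only, and the continuous bat updates (real-valued
  velocities and the ε-random-walk around the best) are intentionally
  absent: the discrete encoding replaces them.
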