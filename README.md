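# batalign

Global pairwise alignment of protein–protein interaction (PPI) networks
with a discretized bat metaheuristic.

## The problem

Given a source network G₁(V₁, E₁) and a larger target network G₂(V₂, E₂),
global network alignment seeks an injective mapping f : V₁ → V₂ — every
protein of the smaller network aligned to a distinct protein of the larger
one — that maximizes cross-species agreement. Such alignments transfer
functional annotation between species and expose conserved interaction
modules. `batalign` is for computational biologists who have two edge
lists (e.g. from BioGRID), optionally BLAST bit-scores between the two
proteomes, and want a scored global alignment from R or the shell.

## The method

**Node similarity.** Sequence and topology are blended into one score
matrix

> S = α·B′ + (1 − α)·(A₁ B′ A₂ᵀ)′,  α ∈ [0, 1]

where B is the (e.g. BLAST bit-score) similarity matrix, A₁ and A₂ the
adjacency matrices, and ′ marks max-normalization to [0, 1]. The triple
product credits a node pair for similar neighbourhoods. Default α = 0.4.

**Search.** A bat is one candidate alignment ("position") plus a binary
"velocity" marking which source nodes may be re-assigned. The population
is seeded by a greedy pass over S (highest-scoring pair first, without
reuse; similarity-free leftovers assigned at random per bat). Each
iteration a bat draws a frequency, binarizes it, derives its velocity
against the global best (agreeing dimensions keep theirs, others fly with
the binarized frequency), and proposes a global-search move (flying nodes
re-drawn from the unclaimed targets) and possibly a local-search move
(flying nodes' targets permuted among themselves). A proposal is accepted
only if it strictly increases the objective — the number of **conserved
edges**, |f(E₁)| — and the bat's loudness beats a uniform draw; acceptance
decays loudness geometrically (θ) and raises the pulse rate
r = r⁰(1 − e^(−γt)) that gates local search. The run stops after T
iterations or a patience of N improvement-free iterations.

**Scores.** EC = |f(E₁)|/|E₁|, ICS = |f(E₁)|/|E₂(G₂(f(V₁)))|, and the
symmetric substructure score

> S³ = |f(E₁)| / (|E₁| + |E₂(G₂(f(V₁)))| − |f(E₁)|),

which penalizes both sparse-to-dense and dense-to-sparse misalignment.
Biological quality is GOC, the sum over aligned pairs of the Jaccard index
of their GO term sets (the mean over annotated pairs is reported too).
Synthetic instances with known ground truth also get node correctness.

## Worked example

```r
library(batalign)

net1 <- generateNetwork("erdos_renyi", n = 60, param = 0.1, seed = 42)
pair <- generatePair(net1, nExtra = 10, rewireP = 0.1,
                     simNoise = 0.2, simDropout = 0.2, seed = 43)
net1
#> PPINetwork with 60 nodes and 165 edges (mean degree 5.500 )
pair
#> SyntheticPair: 60 -> 70 nodes; 16 of 165 copied edges rewired

S   <- blendedSimilarity(pair@scores, net1, pair@net2, alpha = 0.4)
res <- batAlign(net1, pair@net2, S, batParams(), seed = 44)
res
#> BatAlignResult: 122 conserved edges after 11 iterations (stopped on patience)

an  <- generateAnnotations(pair, seed = 45)
alignmentReport(res@alignment, net1, pair@net2,
                an$annot1, an$annot2, pair@trueMap)
#> $conserved: 122   $induced: 156
#> $ec: 0.739  $ics: 0.782  $s3: 0.613
#> $gocSum: 31.8  $gocMean: 0.531
#> $nodeCorrectness: 0.85
```

Reading: of the 165 source edges, 149 survive the 10% rewiring; the
search conserves 122 of them (EC 0.74) while the aligned region of the
target induces 156 edges, giving S³ = 122/(165 + 156 − 122) = 0.61. 85% of
nodes are mapped to their true partners despite 20% similarity noise and
dropout, and aligned pairs share half their GO terms on average
(annotations were generated with 20% term dropout per side).

Real data go through the same surface: `readEdgeList()`,
`readSimilarity()`, `readAnnotations()`, then `blendedSimilarity()` /
`batAlign()` / `alignmentReport()` / `writeAlignment()`.

## Command line

```sh
cli=$(Rscript -e 'cat(system.file("exec", "batalign.R", package = "batalign"))')
Rscript "$cli" synth --model erdos_renyi --n 50 --param 0.12 --extra 5 \
    --rewire 0.1 --sim-noise 0.1 --seed 7 --out-prefix demo
Rscript "$cli" align --net1 demo.net1.tsv --net2 demo.net2.tsv \
    --sim demo.sim.tsv --alpha 0.4 --seed 7 --out demo.aln.tsv --report demo.json
Rscript "$cli" eval --net1 demo.net1.tsv --net2 demo.net2.tsv \
    --alignment demo.aln.tsv --truth demo.truth.tsv --out demo.eval.json
```

Flags can come from a YAML `--config` file; explicit flags win, and every
JSON report echoes the fully resolved configuration and seed.

## File formats

Tab-separated throughout, `#` comments ignored: edge lists (two label
columns), similarity scores (label, label, non-negative score; duplicates
keep the max), GO annotations (label, term ID), alignments (source label,
target label).
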