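---
title: "Completing genome mixtures from partial adjacencies: model, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing genome mixtures from partial adjacencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmcp)
```

## The problem

Bulk sequencing of a tumor reads DNA from many cells at once. Somatic
rearrangements (inversions, translocations, deletions of large segments)
create *novel adjacencies* — junctions between positions that are not
adjacent in the reference genome — and these junctions are what paired-end
mapping detects. Two things are not observed: the genome of origin of each
adjacency (the sample is a mixture of subclones) and the adjacencies that
coverage or mappability missed. `kmcp` treats this as a combinatorial
reconstruction problem: find `k` genomes, each derived from the reference
by rearrangements, whose adjacencies jointly contain the observed multiset,
together with a tree describing their descent from the reference, minimizing
the summed rearrangement distance along the tree.

The model is deliberately copy-neutral: duplications/deletions with copy
number change, point mutations, and measurement errors (false-positive
adjacencies) are out of scope, and all genes are assumed distinct.

## Data model

A **genome** on `n` genes is a set of adjacencies — unordered pairs of gene
extremities (head `gh`, tail `gt`) — in which each extremity appears at most
once. Extremities outside every adjacency are **telomeres**. Adding an edge
`{gt, gh}` for every gene to the genome graph yields the augmented genome
graph, whose components are the chromosomes: cycles are circular, paths
linear. Internally extremities are integer codes (`2g-1` = tail, `2g` =
head), which fixes the deterministic order used for canonical, byte-stable
output everywhere.

A **partial genome** is the same object read as an incomplete observation.
Whether it can be completed under a set of chromosomal conditions is decided
structurally from its augmented components:

* unrestricted or `{circular}`: always completable (each path can be closed
  on its own);
* `{circular, unichromosomal}`: completable iff no component is already a
  closed cycle, unless the genome *is* a single all-gene cycle;
* `{linear}` / `{linear, unichromosomal}`: completable iff no component is a
  cycle (a closed chromosome can never be opened by adding edges).

These rules are not postulated: the test suite checks each of them against
exhaustive enumeration of every matching extension on up to three genes.
`{unichromosomal}` alone is rejected — none of the algorithms here are
defined for it, and silently guessing a rule would be worse than refusing.

A **partial multi-genome** (mixture) is a multiset of adjacencies; its
genome graph is a multigraph whose vertex degrees are unbounded.

## Distance

The package uses the double-cut-and-join (DCJ) distance throughout:
`d(G1,G2) = n − c − p/2`, where `c` counts cycles and `p` counts
*odd-vertex* paths of the breakpoint graph on the `2n` extremities.
Isolated extremities are taken as 1-vertex (odd) paths; with this reading
`d(G,G) = 0` also for genomes with telomeres, and the whole convention is
validated against an independent breadth-first-search oracle over the DCJ
move set: exhaustively for every genome pair on up to 2 genes and on
hundreds of seeded 3-gene pairs. Had the vertex-parity reading been wrong,
that oracle — not the formula — would have flagged it; the suite asserts
their agreement rather than assuming it.

## Single-genome completion

**Unrestricted.** In `B(G, A)` only paths whose two terminal edges are both
reference adjacencies can be closed into new cycles; `complete_unrestricted`
closes exactly those and leaves every other free extremity alone. Joining
other path ends merely concatenates paths and — under the odd-vertex-parity
convention — can *increase* the distance, which is why the solver never
does it. The optimality of this rule, including its interaction with the
odd-path term, is established empirically against the
exhaustive-extension oracle on seeded instances (the cycle argument alone
does not cover the parity term; the oracle does).

**Circular unichromosomal.** The obstruction structure is the
free-extremities graph `R(G, A)` on the free extremities of `G`: blue
(*desired*) edges pair the endpoints of each breakpoint-graph path, red
(*excluded*) edges pair the endpoints of each chromosome path. Both edge
sets are perfect matchings on `F(G)` (hence
`|E(G)| = |D_A(G)| = |F(G)|/2`), so every component is an even alternating
cycle. Adding an adjacency `{u,v}` updates `R`: `u` and `v` disappear and
their blue edges merge (if they *were* the same blue edge, a breakpoint
cycle is banked), likewise the red edges — merging the same red edge closes
the chromosome and is only legal as the last move. The maximum number of
blue-edge updates has the closed form `Nb(R) − c(R) + 1`, which the package
also verifies by exhaustive update-sequence search on small instances. The
solver repeatedly adds *optimal* adjacencies: first cross-cycle pairs until
one component remains, then blue edges until one remains, then the final
red edge. Where several eligible pairs exist the lexicographically smallest
is taken — any optimal choice leads to an optimum, so the tie-break is pure
determinism for reproducibility. Inputs that are already complete are
returned unchanged rather than rejected.

**Linear unichromosomal.** A linear unichromosomal reference has exactly one
excluded edge `e` (joining its two telomeres); adding it gives a circular
reference, the circular solver runs, and one added adjacency is removed:
when `theta(e) = 1` (`e` not on a cycle of `B(G, A_c)`) an added adjacency
sharing `e`'s breakpoint cycle, otherwise any added adjacency. The optima
satisfy `c_circular = c_linear + theta(e)`. Two package-level choices: the
removed edge is always restricted to *added* adjacencies so the output still
contains the input observation (removing an observed adjacency would be a
valid optimum of the abstract problem but useless as a reconstruction), and
among eligible edges the canonical smallest is removed, again for
determinism.

All three solvers are linear-time in the number of genes; the suite runs
them on instances of 50 and 200 genes (structure checks only) and validates
optimality on ~100 seeded instances each with up to 4 genes, where
exhaustive enumeration of completions is feasible (at most 764 matchings on
8 free extremities).

## Mixtures

A mixture `M` splits into `k` genomes iff the edges of its genome graph can
be partitioned into `k` matchings, i.e. iff its chromatic index is at most
`k`. `chromatic_index_at_most` decides this exactly by backtracking over
edges in largest-degree-first order, returning a witness coloring whose
classes are the attributions. The exact search is guarded at 32 edges;
beyond it the answer is only given when the degree lower bound `χ' ≥ Δ`
already decides, and is otherwise an explicit `NA` — a heuristic negative is
never reported, because deciding `χ'` for `Δ ≥ 3` is NP-complete and a
wrong "no" would be indistinguishable from a proof.

`brute_force_kmcp` solves tiny instances exactly: every proper coloring
(deduplicated as unordered class partitions), every condition-satisfying
completion of every class, every labeled mixture tree (Prüfer enumeration on
`k+1` vertices; 3 trees for `k = 2`, 16 for `k = 3`), minimizing the summed
pairwise DCJ distance with memoized distance calls. The guards (`n ≤ 3`,
`k ≤ 3` by default) are arguments, not constants: instances whose genome
graph is a disjoint union of even cycles — exactly what the hardness gadgets
produce — have a single completion per class, so the caller may raise
`max_n` safely there. Mixture-tree vertices are fixed to the reference plus
the `k` genomes; Steiner-type trees with unobserved intermediates are out of
scope. The suite verifies that restricting completions to all-circular
genomes never changes the optimum value (circularizing a completion cannot
destroy breakpoint cycles), and that for `k = 1` the brute force agrees with
the linear-time solvers.

## Hardness constructions

The gadget module makes the negative results constructive. `expand_clause`
turns a 3-literal disjunction into the 7 conjunctions obtained by flipping
literal signs in all ways except negating all three; over the 8 assignments
exactly one conjunction is satisfied iff the clause is, so clause-optimum
equals conjunction-optimum. `build_gadget` renders a conjunction instance as
a mixture: each variable becomes an even cycle of length `4t` (`t` = number
of literal appearances, minimum length 4) whose two perfect matchings encode
true/false; each 3-literal conjunction becomes a 6-cycle of three host edges
(drawn from the true matching for a positive literal, false for negative)
plus three fresh conjunction edges. Host slots advance four edge positions
per appearance, which keeps any two host edges at least three cycle
positions apart — hence no variable-cycle edge ever touches conjunction
edges of two different conjunction-cycles, the separation the construction
needs. All variable-cycle edges form the mixture `M`; the conjunction edges
form the reference `A` (a matching by the spacing argument). Gadget vertices
are allocated as fresh genes — two consecutive cycle vertices per gene — so
`M` and `A` are ordinary genome-world objects.

`3m + 1` single-variable padding conjunctions on fresh variables are added
(`m` = input conjunctions). Their cycles carry no reference edges, and with
`3m + 1` untouched cycles against `3m` reference edges the path tree beats
the branch tree whenever the number of untouched cycles exceeds twice the
number of reference edges. Note the margin: `3m + 1 > 2·(3m)` holds only
for `m = 0`; for `m ≥ 1` the padding count stated with the construction does
not meet that sufficient condition by itself (the remaining `3m` variable
cycles of the real variables also count toward the cycle total `m ≥ ℓ'`
side of the argument). The package therefore does not *assume* path-tree
optimality: the test suite establishes it empirically on the gadgets it
builds, by running the exhaustive solver and checking (a) the optimal tree
is a path tree and (b) the middle genome induces a truth assignment whose
score equals the exhaustive conjunction-satisfaction optimum. One reading
convention in that check: the mixture objective is indifferent to the
padding cycles (both matchings cost the same), so the induced assignment is
scored with padding variables set true — exactly what any optimal assignment
does on the satisfaction side.

## Simulator

`simulate_mixture` generates the study conditions the solvers are tested
under: a reference with a configurable number of linear and circular
chromosomes (uniform gene order/orientation, uniform composition of sizes),
`k` descendants obtained by applying uniformly chosen DCJ moves along the
configured mixture tree, independent Bernoulli masking of each genome's
adjacencies, and pooling into an unattributed multiset with ground truth
retained. Defaults are modest (2 moves per edge, 20% masking) — of the
order of a handful of rearrangements per lineage, and dropout high enough
that completions are nontrivial. Choices worth knowing:

* masking is per-adjacency independent; there is no length-, region- or
  coverage-biased dropout and no false-positive adjacencies — real
  breakpoint calls violate both, so passing tests say nothing about robust
  error handling;
* intermediate scrambled genomes are *not* constrained to the root's
  chromosomal composition: a DCJ move may linearize a circular chromosome
  or split one into two; condition flags describe the generated root only;
* all randomness flows from the single config seed (RNG state is saved and
  restored around every seeded call), so identical configurations are
  byte-identical, including file output via the command-line interface.

Test problem sizes were chosen so each oracle comparison enumerates at most
a few thousand objects: up to 4 genes for completion oracles, 6 edges for
coloring enumeration, 2 variables and one real conjunction for reduction
gadgets. These are the scales at which exhaustive ground truth is cheap and
exact; the solvers themselves run comfortably on hundreds of genes.

## Degenerate inputs and numerical conventions

No floating point is involved anywhere; all quantities are small integers
and all assertions are exact. Degenerate cases are pinned by tests: empty
genomes (all telomeres), single-gene circular chromosomes `{gh, gt}`,
already-complete inputs (returned unchanged), empty mixtures (one valid
coloring with empty classes), and the `m = 0` gadget (a single padding
cycle). Errors are always raised for malformed input — self-pair
adjacencies, extremities used twice, gene indices out of range, duplicate
lines in single-genome files (multiplicity is only meaningful in mixture
files), missing GRIMM terminators — rather than silently repaired.

## Limitations

Weighted or error-tolerant adjacencies, copy-number events, read-level
simulation, enumeration of *all* optimal completions, and polynomial
heuristics for `k ≥ 2` are all out of scope; the exact exponential solver
is intended as ground truth for tiny instances, not as a practical mixture
deconvolver. Distances other than DCJ can be plugged into the exhaustive
solver (`phi` argument) but only DCJ is exercised by the tests.
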