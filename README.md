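# kmcp: reconstructing genome mixtures from partial adjacencies

Bulk DNA sequencing of a heterogeneous tumor measures the novel
adjacencies (breakpoints) produced by somatic genome rearrangements, but
two pieces of information are lost: which subclonal genome each adjacency
belongs to, and the adjacencies that low coverage or repeats failed to
detect. `kmcp` implements exact algorithms for the *k-minimum completion
problem* (k-MCP): given an unattributed, possibly incomplete multiset of
adjacencies pooled from *k* genomes that evolved from a known reference
*A* by rearrangements, reconstruct the *k* genomes and a mixture tree
rooted at *A* that minimize the total rearrangement distance.

The package is aimed at researchers in genome rearrangement theory and
cancer genomics who want a reference implementation of the exact
machinery: the solvers, the existence test, the hardness gadgets, and a
simulator for benchmarking future heuristics.

## The model

A genome on *n* genes is a matching on the 2*n* gene extremities
(head/tail per gene); unmatched extremities are telomeres. Chromosomes
are the components of the genome graph augmented with an edge {g_t, g_h}
per gene: cycles are circular chromosomes, paths linear ones. The
distance is the double-cut-and-join (DCJ) distance

    d_DCJ(G1, G2) = n − c − p/2,

with *c* the cycles and *p* the odd-vertex paths of the breakpoint graph
B(G1, G2). What the package provides:

* **Single-genome completion (1-MCP), exactly and in linear time.**
  Unrestricted: close every breakpoint-graph path whose terminal edges
  are both reference adjacencies. Circular unichromosomal: a greedy
  algorithm on the *free-extremities graph* — blue (desired) edges pair
  breakpoint-path endpoints, red (excluded) edges pair chromosome-path
  endpoints — whose maximum number of blue updates has the closed form
  `Nb − c(R) + 1`. Linear unichromosomal: solved through the circular
  case via the correction term `theta(e) ∈ {1, 2}` for the reference
  adjacency `e` that circularizes the reference.
* **Mixtures (k-MCP).** A k-genome attribution of a mixture exists iff
  the chromatic index of its genome graph is at most *k*
  (`chromatic_index_at_most`, exact backtracking with a witness), and an
  exhaustive exact solver (`brute_force_kmcp`) minimizes the tree value
  over colorings, completions and labeled mixture trees on tiny
  instances. Restricting completions to all-circular genomes provably
  does not change the optimum.
* **Hardness gadgets.** Constructors for the reduction from maximum
  3-conjunction satisfaction to the 2-genome problem: clause expansion
  (7 conjunctions per clause), variable-cycles with true/false matchings,
  6-edge conjunction-cycles, and `3m + 1` padding conjunctions that force
  the optimal mixture tree into path shape.
* **Simulator.** Seeded generation of references, DCJ-scrambled
  descendants along a mixture tree, Bernoulli adjacency masking, and
  pooling with ground-truth attribution.
* **Oracles.** Every polynomial solver ships with the exponential oracle
  it is validated against (BFS move search, exhaustive completion and
  update-sequence enumeration) — usable for your own spot checks.

## Worked example

```r
library(kmcp)

g <- from_signed_permutations(c("2 4 -5 @", "1 -3 $"))
g
#> genome on 5 genes with 4 adjacencies
#>   A = {1h,3h} {2t,5t} {2h,4t} {4h,5h}
#>   telomeres: 1t 3t
chromosomes(g)
#> 2 chromosome(s)
#>   [1] linear, genes: 1 3
#>   [2] circular, genes: 2 4 5
```

The adjacency set records which gene ends are joined; genes 2, 4, 5 form
a circular chromosome, genes 1 and 3 a linear one whose ends (1t, 3t) are
telomeres. Completing a partial observation against a circular reference:

```r
part <- genome(3, "1h 2t")                       # one observed adjacency
ref  <- genome(3, c("1h 2t", "2h 3t", "3h 1t"))  # circular reference
out <- complete_circular(part, ref)
out
#> genome on 3 genes with 3 adjacencies
#>   A = {1t,3h} {1h,2t} {2h,3t}
attr(out, "cycles"); dcj_distance(out, ref)
#> [1] 3
#> [1] 0
```

The completion attains 3 breakpoint cycles — the maximum possible on 3
genes — so the reconstructed genome is at DCJ distance 0 from the
reference, i.e. the observed adjacency is consistent with an unrearranged
circular chromosome. A two-genome mixture:

```r
sim <- simulate_mixture(sim_config(6, n_linear = 0, n_circular = 1,
                                   parents = c(0, 1), moves = 2,
                                   mask = 0.25, seed = 42))
sim
#> simulated mixture: 2 genomes on 6 genes; 10 observed adjacencies
chromatic_index_at_most(sim$mixture, 2)
#> [1] TRUE
#> attr(,"coloring")
#>  [1] 1 2 1 2 1 1 2 1 2 2
```

`TRUE` certifies that the pooled adjacencies can be split into two
genomes; the witness coloring is one such attribution (color classes are
matchings).

A shell interface for all of the above lives in `inst/cli/kmcp.R`
(subcommands `chromosomes`, `dcj-dist`, `complete1`, `kcheck`,
`brute-kmcp`, `reduce-3and`, `simulate`; `--json` for machine-readable
reports).

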