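---
title: "Minimum deep coalescence species trees: model, algorithms, and simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum deep coalescence species trees: model, algorithms, and simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(deepcoal)
```

## The problem

Unlinked genes sampled from the same set of species routinely disagree about
the species phylogeny.  One major biological cause is deep coalescence
(incomplete lineage sorting): gene lineages that fail to coalesce within the
species-tree branch where their species diverged, so that the gene tree's
topology reflects ancestral polymorphism rather than the species branching
order.  The minimum deep coalescence (MDC) criterion turns this into a
parsimony problem: given rooted binary gene trees $T_1, \dots, T_n$ over one
taxon set $X$, find the rooted binary species tree $S$ minimising the
aggregated deep coalescence cost $\sum_i DC(T_i, S)$.

`deepcoal` implements this criterion together with the consensus structure
that makes it tractable at scale: every optimal species tree provably
contains every *consensus cluster* (a clade shared by all gene trees), so
the optimum is always a refinement of the strict consensus tree, and every
multifurcation of the strict consensus can be refined as an independent
subproblem.

## The cost

Each gene-tree node $v$ is mapped to $M(v)$, the least common ancestor in
$S$ of the taxa below $v$ (the LCA mapping).  The cost of a gene-tree edge
$\{u, v\}$ ($u$ the child) is the number of species-tree edges between
$M(u)$ and $M(v)$, and

$$DC(T, S) = \sum_{\{u,v\} \in E(T)} \mathrm{pl}_S\!\big(M(u), M(v)\big).$$

A congruent gene tree ($T = S$, $m$ taxa) already pays $2m - 2$: each
species-tree edge is traversed exactly once.  The classical *extra lineage*
count — lineages beyond the first crossing a species-tree branch when $T$
is embedded in $S$ — satisfies

$$\mathrm{XL}(T, S) = DC(T, S) - (2m - 2),$$

because the edges of the path above $M(u)$ are exactly the species branches
the lineage ending at $u$ traverses, and each branch's first lineage is
free.  The package verifies this identity against an independent
lineage-tracking implementation (`extra_lineages_oracle()`), exhaustively
for all topology pairs up to 5 taxa and on a thousand random larger pairs.
User-facing scores default to the extra-lineage convention (magnitudes
comparable across instance sizes, 0 for perfect congruence); theorems and
internal optimisation use the raw sum, which differs only by a constant per
gene tree, so the two conventions have identical argmin sets.

Rooted trees are represented with the root edge implicit: the stored root is
the child of the conceptual degree-one root.  The root edge contributes 0 to
every cost (the mapping sends both of its endpoints to the species root), an
invariant the test suite checks by materialising the extra root and
re-scoring.  Depths are nevertheless reported in the convention where the
implicit root has depth 0, so the depth arithmetic of the repair guarantee
can be checked verbatim.

## Canonical form

Children of every node are ordered by the lexicographically smallest leaf
label below them, and tree equality is equality of canonical Newick strings.
All tie-breaks downstream (attachment nodes in the repair, equally scoring
SPR neighbours, representative optima) resolve through this order, which is
what makes every search in the package reproducible from a seed.

## Repairing a candidate: shallowest regrouping

Given a candidate species tree $S$ missing a consensus cluster $\chi$, the
*regrouping* edit detaches the subtree spanned by $\chi$ (the restriction
$S|\chi$), attaches its root at a degree-two node $v$ of the
complement-induced tree $S(\bar\chi)$, and suppresses all degree-two nodes.
When $v$ is chosen among the *shallowest* degree-two nodes, the resulting
tree contains $\chi$ and has strictly smaller cost to *every* gene tree
containing $\chi$ — hence strictly smaller aggregated cost.  This is the
engine of both the Pareto guarantee and `improve_candidate()`, which sweeps
the consensus clusters and regroups each missing one.

Two conventions the underlying theory leaves open are fixed as follows:

* **Attachment tie-break.**  Among equally shallow degree-two nodes, the one
  whose subtree holds the smallest leaf label.  Improvement is guaranteed
  for *any* choice; the rule only pins down determinism.
* **Cluster processing order.**  Decreasing cluster size, ties
  lexicographic.  Consensus clusters form a laminar family, and processing
  larger clusters first means each later (nested or disjoint) regroup leaves
  the earlier ones intact; the suite asserts both this retention and that
  *every* processing order still ends Pareto with non-increasing cost.

## Divide and conquer on the strict consensus

`dc_species_tree(method = "divide")` computes the strict consensus $H$
(laminar construction from the intersection of the trees' cluster sets,
cross-checked in the tests against `ape::consensus`), then for every
internal node of $H$ with three or more children solves the *cut* instance:
each gene tree is restricted to one representative leaf per child cluster,
the representatives are renamed to opaque atoms, and the resulting small
profile is handed to a sub-solver.  Because each child cluster is a cluster
of every gene tree, the restriction collapses exactly that clade, and the
cost arithmetic never looks inside the atom labels.  The solved topology
replaces the multifurcation.

The subproblems are pure functions of the profile and the consensus node:
they may be solved in any order (or concurrently) with identical results,
which `dc_consensus_method(node_order = ...)` demonstrates.  With the exact
sub-solver on every subproblem the assembled tree attains the global
optimum; the suite verifies this equivalence on random instances up to 7
taxa against exhaustive search over all $(2m-3)!!$ topologies, and verifies
directly that cutting any global optimum at any consensus node yields an
optimum of the cut instance.

Two conventions fixed here: the cut tree is rooted at the LCA of the child
images (costs are defined on rooted trees, and any other rooting of the
spanning subtree is cost-equivalent after the degree-two suppression, which
is itself verified cost-neutral), and subproblems with at most
`exact_threshold = 8` leaves are solved exactly — the size regime where
exhaustive enumeration (at most $(2 \cdot 8 - 3)!! = 135{,}135$ topologies)
is routine — with the SPR heuristic above it.

## The SPR comparator

`spr_solve()` is a steepest-descent hill climb over the rooted SPR
neighbourhood: prune any subtree, regraft on any edge including the root
edge.  Full neighbourhood scan, strictly improving steps only, ties broken
canonically, optional restarts; the default start is a random binary
refinement of the strict consensus (which starts the search inside the
Pareto set), and `start = "random"` reproduces the classical unconstrained
search.  The neighbourhood-evaluation shortcuts of specialised MDC software
are deliberately not replicated — this solver is the *generic* comparator,
so score comparisons with the divide-and-conquer method are statistical
rather than bit-exact.

One empirical note: on grafted adversarial profiles (below) the full-scan
steepest descent was never observed to terminate in a local optimum missing
the planted consensus cluster (nor was a first-improvement variant), even
though such local optima are what motivate the repair algorithm; the repair
guarantee is therefore exercised in the tests on non-Pareto trees taken
from capped, still-descending searches.

## Simulators

Three generators reproduce the study designs the package is validated on.
All draw from R's RNG; `set.seed()` gives full determinism.

* **Grafted profiles** (`grafted_profile()`): each of (by default) four
  gene trees is a uniform random 11-taxon tree on `s1..s11` whose leaf
  `s11` is replaced by a uniform random 4-taxon tree on `s11..s14`.  All
  trees share the cluster `{s11, s12, s13, s14}` and typically nothing
  else.  This emulates extreme gene-tree conflict, not a biological
  process.
* **Skeleton refinements** (`complete_bary()`, `random_refinement()`): a
  complete $b$-ary tree of depth $d$ as the known consensus, with gene
  trees drawn as independent uniform resolutions of each multifurcation —
  the regime where the divide-and-conquer decomposition shows its largest
  advantage (many medium subproblems instead of one $b^d$-leaf search).
* **Coalescent profiles** (`yule_tree()`, `msc_gene_trees()`): a pure-birth
  species tree conditioned on the taxon count, branch lengths scaled to
  generations (default factor $10^6$), and gene trees simulated under the
  multispecies coalescent with constant population size $N$: within a
  branch of length $L$ generations, $j$ lineages coalesce at rate
  $\binom{j}{2}/(2N)$ per generation (the diploid convention — two lineages
  coalesce in $2N$ generations on average; the factor is configurable via
  `ploidy`), with leftover lineages coalescing in the root population.  The
  rate convention is verified quantitatively in the tests (a cherry whose
  stem is $2N\ln 2$ generations appears in the gene tree with probability
  $2/3$).

### Calibration of the speciation rate

The coalescent study design fixes 256 taxa, 20 gene trees per species tree,
20 replicates, and population sizes $10^4$ and $10^5$, but not the
speciation rate of the pure-birth tree, which (with the $10^6$ scaling)
controls branch lengths in generations and hence the level of incomplete
lineage sorting.  The package calibrates this rate once against the
gene-tree agreement level — the average number of non-trivial clusters
shared by all 20 gene trees — and freezes it at `yule_birth_default()`
(2.15 per lineage per unit time).

The family is effectively one-dimensional: pure-birth branch lengths scale
inversely with the rate, and the coalescent depends on branch lengths only
through $L/(2N)$, so the rate and the population size trade off exactly.
Consequently the two agreement levels at $N = 10^4$ and $N = 10^5$ cannot
be set independently: across the whole rate range the shared-cluster count
drops by at least threefold per tenfold increase in $N$.  The calibration
therefore targets the high-ILS agreement level (about 19 shared clusters at
$N = 10^5$); at the same rate the low-ILS condition ($N = 10^4$) yields a
much higher agreement level (about 190 shared clusters) — gene trees that
are nearly congruent with the species tree, as their per-tree extra-lineage
costs also show.  What passing simulations show about real data is limited
accordingly: the generator produces clock-like trees, one gene copy per
species, constant $N$, no migration, hybridisation, or gene-tree estimation
error.

## Numerical and scale choices

Everything cost-related is exact integer arithmetic; there are no numerical
tolerances in the criterion itself.  Exhaustive enumeration is guarded at 8
taxa by default (9 at most); the SPR climb evaluates $\Theta(m^2)$
neighbours per step with an $O(nm)$ exact re-score each, so standalone SPR
is practical here to a few dozen taxa, while the divide-and-conquer method
scales with the largest multifurcation of the strict consensus rather than
with the taxon count.  The test suite validates the solver stack
exhaustively at small sizes (all 4-taxon instance pairs; random instances
to 8 taxa; two-level optimality checks to 7 taxa), runs the coalescent
agreement summaries at the full stated scale (256 taxa), and benchmarks the
divide-vs-SPR score comparison at 32 taxa with 8 gene trees — the size at
which the generic standalone comparator is comfortable — where the two
methods' scores agree or differ by a bounded amount, and the
divide-and-conquer tree always contains every consensus cluster.

## Known limitations

* Consensus setting only: all gene trees must cover the identical taxon
  set (no supertree inputs), be rooted, and be binary.
* Purely topological: branch lengths are parsed and carried but never enter
  any cost.
* The repair and the Pareto guarantee are only informative when the gene
  trees share clusters; with no consensus clusters the divide-and-conquer
  method degenerates to a single full-size subproblem.
* The SPR comparator is deliberately generic; it does not reproduce the
  per-move shortcuts (or the failure anecdotes) of specialised MDC
  implementations.
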