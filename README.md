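# deepcoal

Species-tree inference from gene trees under the **minimum deep
coalescence (MDC)** criterion, for phylogeneticists working with
multi-locus data where incomplete lineage sorting makes gene trees
disagree with each other and with the species phylogeny.

Given rooted binary gene trees $T_1,\dots,T_n$ over one taxon set, the MDC
species tree is

$$\hat S \;=\; \arg\min_{S} \sum_{i=1}^{n} DC(T_i, S),
\qquad
DC(T,S) \;=\; \sum_{\{u,v\}\in E(T)} \mathrm{pl}_S\big(M_{T\triangleright S}(u),\, M_{T\triangleright S}(v)\big),$$

where $M_{T\triangleright S}$ is the LCA mapping of gene-tree nodes into
$S$ and $\mathrm{pl}_S$ counts species-tree edges between the images.
Equivalently, $DC(T,S) - (2m-2)$ is the classical number of *extra
lineages* implied by embedding $T$ in $S$.

The package's distinguishing feature is the consensus structure of this
problem, exposed as working algorithms:

* **Pareto guarantee** — every optimal species tree contains every
  *consensus cluster* (clade shared by all gene trees).  `is_pareto()`
  checks it; `improve_candidate()` repairs any candidate that violates it,
  by "shallowest regrouping" edits that strictly lower the cost to every
  gene tree.
* **Divide and conquer** — each multifurcation of the strict consensus is
  an independent subproblem.  `dc_species_tree(method = "divide")` refines
  them separately (exactly up to 8 taxa per subproblem, rooted-SPR hill
  climbing above), so the search scales with the largest unresolved node
  of the consensus rather than with the total taxon count.
* **Solvers and simulators** — exhaustive exact search
  (`exact_solve()`), a generic rooted-SPR heuristic (`spr_solve()`), and
  generators for adversarial grafted profiles, b-ary skeleton
  refinements, and Yule + multispecies-coalescent gene trees
  (`yule_tree()`, `msc_gene_trees()`).

## Worked example

Four gene trees over six taxa, congruent about `{a,b}` and `{e,f}` but in
conflict about `c` and `d`:

```r
library(deepcoal)
genes <- dc_profile(list(
  parse_newick("(((a,b),(c,d)),(e,f));"),
  parse_newick("((((a,b),c),d),(e,f));"),
  parse_newick("(((a,b),(d,c)),(f,e));"),
  parse_newick("((((a,b),d),c),(e,f));")
))
write_newick(strict_consensus(genes))
#> [1] "(((a,b),c,d),(e,f));"

fit <- dc_species_tree(genes)
fit
#> Minimum deep coalescence species tree (method: divide)
#>   gene trees: 4  taxa: 6
#>   score: 2 extra lineages (raw 42)
#>   contains all consensus clusters: TRUE
#>   tree: (((a,b),(c,d)),(e,f));
```

The strict consensus leaves one multifurcation (`c`, `d` unresolved against
the `{a,b}` clade); the divide-and-conquer fit resolves it at a total cost
of 2 extra lineages — one each for the two gene trees that placed `c` and
`d` as a ladder instead of a cherry — and, as always, retains every
consensus cluster.  Costs of single gene trees against the fit:

```r
dc_cost(genes$trees[[2]], fit$tree)
#> Deep coalescence cost (6 taxa)
#>   raw path-length sum: 11
#>   extra lineages:      1
```

A deliberately bad candidate is repaired, not re-searched:

```r
improve_candidate(genes, parse_newick("((((e,a),b),(c,d)),f);"))
#> Repaired candidate with 2 regrouping step(s)
#>   aggregated raw cost: 54 -> 42
```

A command-line front end covering the same operations (`cost`,
`consensus`, `repair`, `solve`, `simulate`) is installed at
`inst/scripts/dctree`.

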