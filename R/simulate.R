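# Simulators for the three study designs the package is exercised on:
# grafted gene-tree profiles sharing one 4-taxon cluster, random binary
# refinements of complete b-ary consensus skeletons, and
# multispecies-coalescent gene trees on Yule species trees.  All generators
# draw from R's RNG stream; call set.seed() for reproducibility.

#' Uniform random rooted binary tree
#'
#' Sequential leaf insertion on a uniformly chosen edge (including the root
#' edge), which yields the uniform distribution over the `(2m-3)!!` rooted
#' binary topologies.
#'
#' @param labels Character vector of at least 2 leaf labels.
#' @return A `phylo` tree (canonical form, no branch lengths).
#' @examples
#' set.seed(1)
#' random_binary_tree(letters[1:5])
#' @export
random_binary_tree <- function(labels) {
  labels <- unique(labels)
  if (length(labels) < 2L) stop("need at least 2 labels")
  phylo_from_nest(rtopology_nest(labels))
}

#' Grafted gene-tree profile sharing one 4-taxon cluster
#'
#' Each tree is built from a random 11-taxon tree on `s1..s11` and a random
#' 4-taxon tree on `s11..s14`; the leaf `s11` of the former is replaced by
#' the latter, giving 14-taxon gene trees that all contain the cluster
#' `{s11, s12, s13, s14}` but typically agree on little else.  This is a
#' deliberately adversarial profile (few consensus clusters), not a model of
#' a biological process.
#'
#' @param n_trees Number of gene trees (default 4).
#' @param graft_leaf Which of `s1..s11` to replace (default `"s11"`).
#' @return A [dc_profile()] of 14-taxon binary trees.
#' @export
grafted_profile <- function(n_trees = 4L, graft_leaf = "s11") {
  stopifnot(n_trees >= 1L)
  base_labels <- paste0("s", 1:11)
  graft_labels <- paste0("s", 11:14)
  stopifnot(graft_leaf %in% base_labels)
  trees <- lapply(seq_len(n_trees), function(i) {
    big <- rtopology_nest(base_labels)
    small <- rtopology_nest(graft_labels)
    subst <- function(x) {
      if (nest_is_leaf(x)) {
        if (x == graft_leaf) return(small)
        return(x)
      }
      lapply(x, subst)
    }
    phylo_from_nest(subst(big))
  })
  dc_profile(trees)
}

#' Complete b-ary consensus skeleton
#'
#' The tree `C[d,b]` in which every internal node has exactly `b` children
#' and every leaf sits at depth `d`; it has `b^d` leaves, labelled
#' deterministically `t001, t002, ...`.
#'
#' @param d Depth (>= 1).
#' @param b Branch factor (>= 2).
#' @return A (multifurcating for `b > 2`) `phylo` tree.
#' @export
complete_bary <- function(d, b) {
  stopifnot(d >= 1L, b >= 2L)
  n <- b^d
  labels <- sprintf(paste0("t%0", max(3L, nchar(n)), "d"), seq_len(n))
  k <- 0L
  build <- function(depth) {
    if (depth == 0L) {
      k <<- k + 1L
      return(labels[k])
    }
    lapply(seq_len(b), function(i) build(depth - 1L))
  }
  phylo_from_nest(build(d))
}

# resolve every multifurcation of a nest by a uniform random binary tree
# over its children
random_refinement_nest <- function(x) {
  if (nest_is_leaf(x)) return(x)
  kids <- lapply(x, random_refinement_nest)
  k <- length(kids)
  if (k == 2L) return(kids)
  shape <- rtopology_nest(as.character(seq_len(k)))
  subst <- function(y) {
    if (nest_is_leaf(y)) return(kids[[as.integer(y)]])
    lapply(y, subst)
  }
  subst(shape)
}

#' Random binary refinement of a tree
#'
#' Every multifurcation is independently resolved by a uniform random binary
#' tree over its children, so the result refines the input; a binary input
#' is returned unchanged.
#'
#' @param h A `phylo` tree.
#' @return A rooted binary `phylo` tree refining `h`.
#' @export
random_refinement <- function(h) {
  phylo_from_nest(random_refinement_nest(as_nest(h)))
}

#' Yule (pure-birth) species tree with branch lengths in generations
#'
#' Simulates a pure-birth tree conditioned on `n_taxa` tips via
#' [ape::rphylo()] (death rate 0) and multiplies all branch lengths by
#' `scale` to express them in generations.  The default speciation rate was
#' calibrated once, against the gene-tree agreement levels the
#' multispecies-coalescent study design targets at population sizes 1e4 and
#' 1e5 (see the methods vignette), and is fixed thereafter.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth Speciation rate per lineage per unit time.
#' @param scale Factor converting simulation time to generations
#'   (default 1e6).
#' @return An ultrametric `phylo` with `edge.length` in generations and tip
#'   labels `t001, t002, ...`.
#' @export
yule_tree <- function(n_taxa, birth = yule_birth_default(), scale = 1e6) {
  stopifnot(n_taxa >= 2L, birth > 0, scale > 0)
  phy <- ape::rphylo(n_taxa, birth = birth, death = 0)
  phy$edge.length <- phy$edge.length * scale
  phy$tip.label <- sprintf(paste0("t%0", max(3L, nchar(n_taxa)), "d"),
                           seq_len(n_taxa))
  phy
}

#' @rdname yule_tree
#' @export
yule_birth_default <- function() 2.15

#' Multispecies-coalescent gene trees on a species tree
#'
#' Simulates `k` gene-tree topologies under the multispecies coalescent:
#' one gene copy enters at each tip; within every species-tree branch of
#' length `L` generations, `j` lineages coalesce at rate
#' `choose(j, 2) / (ploidy * N)` per generation (continuous-time
#' approximation), and lineages still distinct at the root coalesce in the
#' root's ancestral population.  No migration or hybridisation.  Branch
#' lengths are dropped from the output: every downstream cost is
#' topological.
#'
#' @param stree An ultrametric `phylo` with `edge.length` in generations.
#' @param N Constant (effective) population size per branch (>= 1).
#' @param k Number of gene trees (>= 1).
#' @param ploidy Ploidy factor of the coalescence rate denominator
#'   (default 2: two lineages coalesce in `2N` generations on average).
#' @return A `multiPhylo` of `k` rooted binary topologies on the tips of
#'   `stree`.
#' @export
msc_gene_trees <- function(stree, N, k, ploidy = 2) {
  stopifnot(inherits(stree, "phylo"), !is.null(stree$edge.length),
            N >= 1, k >= 1, ploidy > 0)
  ntip <- length(stree$tip.label)
  kids <- split(seq_len(nrow(stree$edge)), stree$edge[, 1])
  blen_of <- numeric(ntip + stree$Nnode)
  blen_of[stree$edge[, 2]] <- stree$edge.length
  root <- ntip + 1L
  one <- function() {
    sim <- function(v) {
      lin <- if (v <= ntip) list(stree$tip.label[v])
        else unlist(lapply(kids[[as.character(v)]], function(e)
          sim(stree$edge[e, 2])), recursive = FALSE)
      coalesce(lin, if (v == root) Inf else blen_of[v])
    }
    coalesce <- function(lin, L) {
      j <- length(lin)
      t <- 0
      while (j > 1L) {
        t <- t + stats::rexp(1L, rate = j * (j - 1) / 2 / (ploidy * N))
        if (t > L) break
        pair <- sample.int(j, 2L)
        merged <- list(lin[[pair[1]]], lin[[pair[2]]])
        lin <- c(lin[-pair], list(merged))
        j <- j - 1L
      }
      lin
    }
    nest_newick(sim(root)[[1]])
  }
  txt <- vapply(seq_len(k), function(i) one(), character(1))
  trees <- ape::read.tree(text = txt)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

#' Shared non-trivial cluster count of simulated gene trees
#'
#' Convenience summary used by the coalescent study design: the number of
#' non-trivial clusters common to all gene trees of a profile.
#'
#' @param trees A list of trees or [dc_profile()].
#' @return Integer count.
#' @export
shared_cluster_count <- function(trees) {
  length(consensus_keys(dc_profile(trees), nontrivial = TRUE))
}
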