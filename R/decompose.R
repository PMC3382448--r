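# Divide and conquer on the strict consensus.  Every internal node of the
# strict consensus defines an independent subproblem: cut each gene tree to
# the subtree spanning the images of that node's children (each image is a
# subtree root because the children's clusters are consensus clusters),
# collapse the images to set-labelled leaves, solve the small consensus
# instance, and graft the solved topology back in place of the
# multifurcation.  Solving every subproblem exactly solves the full problem
# exactly; the subproblems may be processed in any order.

#' Cut a refining tree at an internal consensus node
#'
#' Extracts the subproblem defined by internal node `h` of `h_tree`: the
#' subtree of `t` spanning the images of `h`'s children, with each image
#' collapsed to a fresh atomic leaf standing for its taxon set, degree-two
#' nodes suppressed, rooted at the LCA of the images.
#'
#' @param h_tree A (possibly multifurcating) `phylo` tree.
#' @param h Internal node of `h_tree` (ape index, i.e. `> Ntip`).
#' @param t A rooted binary `phylo` tree over the same leaf set that refines
#'   `h_tree`.
#' @return A list with `tree` (a `phylo` over atom labels `c1`, `c2`, ...)
#'   and `sets` (named list: atom label -> character vector of taxa).
#' @examples
#' H <- parse_newick("((a,b),c,d);")
#' cut_tree(H, tree_lca(H, c("a", "b", "c", "d")), parse_newick("((a,b),(c,d));"))
#' @export
cut_tree <- function(h_tree, h, t) {
  stopifnot(inherits(h_tree, "phylo"))
  ntip <- length(h_tree$tip.label)
  if (h <= ntip || h > ntip + h_tree$Nnode) {
    stop("'h' must be an internal node of 'h_tree'")
  }
  if (!refines(t, h_tree)) stop("'t' does not refine 'h_tree'")
  kids <- h_tree$edge[h_tree$edge[, 1] == h, 2]
  child_sets <- lapply(kids, function(k) {
    if (k <= ntip) h_tree$tip.label[k]
    else sort(ape::extract.clade(h_tree, k)$tip.label)
  })
  cut_from_sets(t, child_sets)
}

# shared worker: cut t by a list of disjoint taxon sets
cut_from_sets <- function(t, child_sets) {
  o <- order(vapply(child_sets, min, character(1)), method = "radix")
  child_sets <- child_sets[o]
  atoms <- sprintf("c%02d", seq_along(child_sets))
  reps <- vapply(child_sets, min, character(1))
  nest <- as_nest(t)
  cutn <- nest_restrict(nest, reps)
  relab <- function(x) {
    if (nest_is_leaf(x)) return(atoms[match(x, reps)])
    lapply(x, relab)
  }
  sets <- child_sets
  names(sets) <- atoms
  list(tree = phylo_from_nest(relab(cutn)), sets = sets)
}

#' Cut an entire profile at a consensus node
#'
#' Applies [cut_tree()] to every tree of the profile at internal node `h` of
#' the strict consensus `h_tree`.  Each child cluster of `h` must be a
#' cluster of every gene tree (which holds exactly when `h_tree` is the
#' profile's strict consensus); collapsing it to a leaf is then well defined
#' in every tree.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param h_tree The strict consensus of `profile`.
#' @param h Internal node of `h_tree` (ape index).
#' @return A list with `profile` (a [dc_profile()] over atom labels) and
#'   `sets` (atom -> taxon set).
#' @export
cut_instance <- function(profile, h_tree, h) {
  profile <- dc_profile(profile)
  stopifnot(inherits(h_tree, "phylo"))
  ntip <- length(h_tree$tip.label)
  if (h <= ntip || h > ntip + h_tree$Nnode) {
    stop("'h' must be an internal node of 'h_tree'")
  }
  kids <- h_tree$edge[h_tree$edge[, 1] == h, 2]
  child_sets <- lapply(kids, function(k) {
    if (k <= ntip) h_tree$tip.label[k]
    else sort(ape::extract.clade(h_tree, k)$tip.label)
  })
  # every child cluster must be present in every gene tree
  for (i in seq_len(profile$n)) {
    have <- nest_cluster_keys(profile$nests[[i]], profile$taxa)
    for (cs in child_sets) {
      if (!cluster_key(match(cs, profile$taxa)) %in% have) {
        stop("'h_tree' is not the strict consensus of the profile: cluster {",
             paste(cs, collapse = ","), "} is absent from tree ", i)
      }
    }
  }
  cuts <- lapply(profile$nests, function(nst) {
    cut_from_sets(phylo_from_nest(nst), child_sets)
  })
  list(profile = dc_profile(lapply(cuts, `[[`, "tree")),
       sets = cuts[[1]]$sets)
}

#' Divide-and-conquer deep coalescence search on the strict consensus
#'
#' Computes the strict consensus of the profile, then independently refines
#' every multifurcation: the cut instance at each internal node with three or
#' more children is handed to a sub-solver, and the solved topology replaces
#' the multifurcation.  With an exact sub-solver on every subproblem the
#' assembled tree attains the global optimum; the output always contains
#' every consensus cluster.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param solver `"auto"` (exact up to `exact_threshold` leaves, SPR above),
#'   `"exact"`, `"spr"`, or a function `(dc_profile) -> phylo` implementing
#'   the sub-solver contract.
#' @param exact_threshold Subproblem size (leaves) up to which the exact
#'   solver is used when `solver = "auto"`.
#' @param restarts,seed Passed to [spr_solve()] for heuristic subproblems.
#' @param node_order Optional permutation of the subproblem indices; the
#'   result is identical for every order (the subproblems are disjoint),
#'   which this argument exists to demonstrate.
#' @return A list with `tree` (the fitted binary `phylo`), `score_raw`,
#'   `score_extra`, and `subproblems` (data frame of per-node subproblem
#'   sizes and solver used).
#' @export
dc_consensus_method <- function(profile, solver = c("auto", "exact", "spr"),
                                exact_threshold = 8L, restarts = 1L,
                                seed = NULL, node_order = NULL) {
  profile <- dc_profile(profile)
  if (!is.null(seed)) set.seed(seed)
  solver_fun <- make_sub_solver(solver, exact_threshold, restarts)
  H <- strict_consensus_nest(profile)
  # collect multifurcating nodes of H as child-set lists, by stable id
  jobs <- list()
  walk <- function(x) {
    if (nest_is_leaf(x)) return(invisible())
    if (length(x) > 2L) {
      jobs[[length(jobs) + 1L]] <<- lapply(x, nest_leaves)
    }
    for (ch in x) walk(ch)
    invisible()
  }
  walk(H)
  order_idx <- if (is.null(node_order)) seq_along(jobs) else node_order
  stopifnot(setequal(order_idx, seq_along(jobs)))
  solved <- vector("list", length(jobs))
  sizes <- integer(length(jobs))
  used <- character(length(jobs))
  for (j in order_idx) {
    child_sets <- lapply(jobs[[j]], function(l) sort(l))
    cuts <- lapply(profile$nests, function(nst) {
      cut_from_sets(phylo_from_nest(nst), child_sets)
    })
    sub <- dc_profile(lapply(cuts, `[[`, "tree"))
    sizes[j] <- sub$m
    res <- solver_fun(sub)
    used[j] <- res$method
    # map atoms back to child taxon sets; store as key -> solved nest
    sets <- cuts[[1]]$sets
    solved[[j]] <- list(
      key = job_key(jobs[[j]]),
      nest = as_nest(res$tree),
      sets = sets
    )
  }
  by_key <- solved
  names(by_key) <- vapply(solved, `[[`, character(1), "key")
  # assemble: replace every multifurcation by its solved topology, with each
  # atom leaf substituted by the (recursively assembled) child subtree
  assemble <- function(x) {
    if (nest_is_leaf(x)) return(x)
    kids <- lapply(x, assemble)
    if (length(kids) == 2L) return(kids)
    sol <- by_key[[job_key(lapply(x, nest_leaves))]]
    child_of_atom <- lapply(sol$sets, function(s) {
      kids[[which(vapply(x, function(k)
        setequal(nest_leaves(k), s), logical(1)))]]
    })
    subst <- function(y) {
      if (nest_is_leaf(y)) return(child_of_atom[[y]])
      lapply(y, subst)
    }
    subst(sol$nest)
  }
  fit_nest <- canon_nest(assemble(H))
  se <- enc_from_nest(fit_nest, profile$taxa)
  raw <- agg_raw(profile, se)
  list(
    tree = phylo_from_nest(fit_nest),
    score_raw = raw,
    score_extra = raw - profile$n * (2L * profile$m - 2L),
    subproblems = data.frame(size = sizes, solver = used,
                             stringsAsFactors = FALSE)
  )
}

job_key <- function(child_leaf_sets) {
  paste(sort(vapply(child_leaf_sets, function(l)
    paste(sort(l), collapse = "\r"), character(1))), collapse = "\n")
}

make_sub_solver <- function(solver, exact_threshold, restarts) {
  if (is.function(solver)) {
    return(function(sub) list(tree = solver(sub), method = "custom"))
  }
  solver <- match.arg(solver, c("auto", "exact", "spr"))
  function(sub) {
    if (sub$m == 2L) {
      return(list(tree = sub$trees[[1]], method = "exact"))
    }
    use_exact <- switch(solver,
      exact = TRUE,
      spr = FALSE,
      auto = sub$m <= min(exact_threshold, 9L)
    )
    if (use_exact) {
      res <- exact_solve(sub, guard = 9L)
      list(tree = res$trees[[1]], method = "exact")
    } else {
      res <- spr_solve(sub, start = "consensus-refinement",
                       restarts = restarts)
      list(tree = res$trees[[1]], method = "spr")
    }
  }
}
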