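#' Parse a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants used
#' throughout the package: a single rooted tree, non-empty pairwise distinct
#' leaf labels.  Multifurcations are preserved; branch lengths, if present,
#' are kept but ignored by all cost computations.
#'
#' @param text A Newick string (terminating `;`).
#' @return A `phylo` tree.
#' @examples
#' parse_newick("((a,b),c);")
#' @export
parse_newick <- function(text) {
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("malformed Newick string: ", text)
  }
  check_labels(phy$tip.label)
  phy
}

check_labels <- function(labs) {
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    stop("every leaf must carry a non-empty label")
  }
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  invisible(labs)
}

#' Write a tree as canonical Newick
#'
#' Children are ordered by the lexicographically smallest leaf label in their
#' subtree, so isomorphic trees serialise identically and string equality of
#' canonical Newick is tree equality.  Branch lengths are not written: the
#' deep coalescence machinery is purely topological.
#'
#' @param phy A `phylo` tree (or Newick string).
#' @param file Optional path; when given the string is written there.
#' @return The canonical Newick string, invisibly when `file` is given.
#' @examples
#' write_newick(parse_newick("(c,(b,a));"))  # "((a,b),c);"
#' @export
write_newick <- function(phy, file = NULL) {
  s <- nest_newick(as_nest(phy))
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read / write a profile of trees (one Newick per line)
#'
#' @param file Path to a Newick file, one rooted tree per line.
#' @return For `read_tree_profile`, a `multiPhylo` list of trees.
#' @export
read_tree_profile <- function(file) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(trees) || length(trees) == 0L) {
    stop("no trees found in ", file)
  }
  for (t in trees) check_labels(t$tip.label)
  trees
}

#' @rdname read_tree_profile
#' @param trees A list of `phylo` trees.
#' @export
write_tree_profile <- function(trees, file) {
  trees <- as_tree_list(trees)
  writeLines(vapply(trees, write_newick, character(1)), file)
  invisible(file)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (is.list(trees)) return(trees)
  stop("expected a tree, a list of trees, or a multiPhylo")
}

#' Clusters (clades) of a rooted tree
#'
#' The cluster of a node is the set of leaf labels below it; a cluster is
#' trivial when it is a singleton or the full leaf set.  A binary tree on m
#' leaves has 2m-1 clusters.
#'
#' @param phy A `phylo` tree (multifurcations allowed).
#' @param nontrivial If `TRUE`, only non-trivial clusters are returned.
#' @return A list of character vectors (sorted labels), one per cluster.
#' @examples
#' tree_clusters(parse_newick("((a,b),c);"))
#' @export
tree_clusters <- function(phy, nontrivial = FALSE) {
  nest <- as_nest(phy)
  taxa <- sort(nest_leaves(nest))
  keys <- nest_cluster_keys(nest, taxa, nontrivial = nontrivial)
  lapply(keys, function(k) taxa[key_to_ids(k)])
}

#' Least common ancestor of a set of taxa
#'
#' @param phy A `phylo` tree.
#' @param taxa Non-empty character vector of leaf labels.
#' @return The node index (ape convention: tips `1..m`, internals from `m+1`).
#' @export
tree_lca <- function(phy, taxa) {
  stopifnot(inherits(phy, "phylo"))
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("taxa must be non-empty")
  idx <- match(taxa, phy$tip.label)
  if (anyNA(idx)) {
    stop("label(s) not in tree: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(phy, idx)
}

#' Restricted subtree
#'
#' Returns `T|X`: the subtree induced by the taxa in `taxa` with all
#' degree-two nodes suppressed, i.e. the usual pruned tree rooted at the LCA
#' of `taxa`.
#'
#' @param phy A `phylo` tree.
#' @param taxa Character vector of at least two leaf labels.
#' @return A `phylo` tree on exactly `taxa`.
#' @examples
#' write_newick(restrict_tree(parse_newick("((a,b),(c,d));"), c("a", "c")))
#' @export
restrict_tree <- function(phy, taxa) {
  nest <- as_nest(phy)
  labs <- nest_leaves(nest)
  miss <- setdiff(taxa, labs)
  if (length(miss)) stop("label(s) not in tree: ", paste(miss, collapse = ", "))
  if (length(unique(taxa)) < 2L) stop("restriction needs at least two taxa")
  phylo_from_nest(nest_restrict(nest, unique(taxa)))
}

#' Induced subtree retaining degree-two nodes
#'
#' Returns the subtree induced by `taxa` *without* suppressing degree-two
#' nodes, together with the depths of those nodes.  Depths follow the
#' convention that the (never materialised) degree-one root sits at depth 0,
#' so the stored root has depth 1.  When `taxa` is a proper non-empty subset
#' of the leaves the degree-two list is non-empty.
#'
#' @inheritParams restrict_tree
#' @param taxa Character vector: non-empty proper subset of the leaf set.
#' @return A list with `tree` (a `phylo` possibly containing unbranched
#'   internal nodes) and `degree2_depths` (sorted integer vector).
#' @export
induced_subtree <- function(phy, taxa) {
  nest <- as_nest(phy)
  labs <- sort(nest_leaves(nest))
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("taxa must be non-empty")
  if (length(setdiff(taxa, labs))) {
    stop("label(s) not in tree: ", paste(setdiff(taxa, labs), collapse = ", "))
  }
  if (setequal(taxa, labs)) {
    stop("taxa must be a proper subset of the leaf set")
  }
  enc <- enc_from_nest(nest, labs)
  ind <- enc_induced(enc, match(taxa, labs))
  nwk <- paste0(induced_nwk(enc, ind), ";")
  list(
    tree = ape::read.tree(text = nwk),
    degree2_depths = sort.int(ind$depth[ind$deg2])
  )
}

# Induced-subtree bookkeeping on an enc.  keep_tax: integer taxon ids.
# Returns kept-node mask, per-node kept-children lists, degree-two node ids
# and their depths in the classical convention (implicit root at depth 0).
enc_induced <- function(enc, keep_tax) {
  nn <- length(enc$par)
  keep <- logical(nn)
  for (v in which(enc$leaf %in% keep_tax)) {
    while (v != 0L && !keep[v]) {
      keep[v] <- TRUE
      v <- enc$par[v]
    }
  }
  kids <- vector("list", nn)
  for (v in which(keep)) {
    p <- enc$par[v]
    if (p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  nkid <- vapply(seq_len(nn), function(v) length(kids[[v]]), integer(1))
  deg2 <- which(keep & nkid == 1L)
  depth <- enc_depths(enc) + 1L
  list(keep = keep, kids = kids, deg2 = deg2, depth = depth)
}

induced_nwk <- function(enc, ind) {
  build <- function(v) {
    if (enc$leaf[v] > 0L) return(enc$taxa[enc$leaf[v]])
    parts <- vapply(ind$kids[[v]], build, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  build(enc_root(enc))
}

#' Does one tree refine another?
#'
#' `TRUE` when every cluster of `h` is a cluster of `t`, i.e. `t` resolves
#' the multifurcations of `h`.
#'
#' @param t,h `phylo` trees over the same leaf set.
#' @return Logical scalar.
#' @export
refines <- function(t, h) {
  tn <- as_nest(t)
  hn <- as_nest(h)
  taxa <- sort(nest_leaves(tn))
  if (!setequal(taxa, nest_leaves(hn))) {
    stop("trees must share one leaf set")
  }
  all(nest_cluster_keys(hn, taxa) %in% nest_cluster_keys(tn, taxa))
}

#' Validate a gene-tree profile
#'
#' A profile is an ordered tuple of rooted *binary* trees over one common
#' leaf set: the unit of input for every consensus and solver routine here.
#'
#' @param trees A `multiPhylo`, list of `phylo`, or single tree.
#' @return An object of class `dc_profile`: the validated trees plus their
#'   internal encodings and the sorted common taxon set.
#' @examples
#' p <- dc_profile(list(parse_newick("((a,b),c);"), parse_newick("((a,c),b);")))
#' p
#' @export
dc_profile <- function(trees) {
  if (inherits(trees, "dc_profile")) return(trees)
  trees <- as_tree_list(trees)
  if (length(trees) < 1L) stop("a profile needs at least one tree")
  nests <- lapply(trees, as_nest)
  taxa <- sort(nest_leaves(nests[[1]]))
  check_labels(taxa)
  if (length(taxa) < 2L) stop("a profile needs at least two taxa")
  for (i in seq_along(nests)) {
    labs <- nest_leaves(nests[[i]])
    check_labels(labs)
    if (!setequal(labs, taxa)) {
      off <- c(setdiff(labs, taxa), setdiff(taxa, labs))
      stop("tree ", i, " has a different leaf set (offending label(s): ",
           paste(off, collapse = ", "), ")")
    }
    if (!nest_is_binary(nests[[i]])) {
      stop("tree ", i, " is not binary")
    }
  }
  enc <- lapply(nests, enc_from_nest, taxa = taxa)
  structure(
    list(
      trees = lapply(nests, phylo_from_nest),
      nests = nests,
      enc = enc,
      taxa = taxa,
      n = length(nests),
      m = length(taxa)
    ),
    class = "dc_profile"
  )
}

nest_is_binary <- function(x) {
  if (nest_is_leaf(x)) return(TRUE)
  length(x) == 2L && all(vapply(x, nest_is_binary, logical(1)))
}

#' @export
print.dc_profile <- function(x, ...) {
  cat("Gene-tree profile: ", x$n, " binary trees over ", x$m, " taxa\n",
      sep = "")
  show <- utils::head(x$taxa, 8L)
  cat("  taxa: ", paste(show, collapse = ", "),
      if (x$m > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# internal: lists of (par, leaf) for the C++ kernels
profile_gpar <- function(profile) lapply(profile$enc, `[[`, "par")
profile_gleaf <- function(profile) lapply(profile$enc, `[[`, "leaf")

# encode an arbitrary tree over the profile's taxa
profile_encode <- function(profile, tree) {
  nest <- as_nest(tree)
  labs <- nest_leaves(nest)
  if (!setequal(labs, profile$taxa)) {
    off <- c(setdiff(labs, profile$taxa), setdiff(profile$taxa, labs))
    stop("tree leaf set differs from the profile (offending label(s): ",
         paste(off, collapse = ", "), ")")
  }
  enc_from_nest(nest, profile$taxa)
}
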