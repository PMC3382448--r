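#' Consensus clusters of a profile
#'
#' The clusters present in every tree of the profile.  The `m + 1` trivial
#' clusters (singletons and the full leaf set) are always shared; counts
#' reported elsewhere in the package use the non-trivial convention, since
#' trivial clusters carry no grouping information.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param nontrivial If `TRUE`, only non-trivial consensus clusters are
#'   returned.
#' @return A list of character vectors (sorted labels).
#' @export
consensus_clusters <- function(profile, nontrivial = FALSE) {
  profile <- dc_profile(profile)
  keys <- consensus_keys(profile, nontrivial = nontrivial)
  lapply(keys, function(k) profile$taxa[key_to_ids(k)])
}

# internal: consensus clusters as taxon-id keys
consensus_keys <- function(profile, nontrivial = FALSE) {
  sets <- lapply(profile$nests, nest_cluster_keys, taxa = profile$taxa,
                 nontrivial = nontrivial)
  Reduce(intersect, sets)
}

#' Strict consensus tree
#'
#' The unique (possibly multifurcating) tree whose cluster set is exactly the
#' set of clusters common to all trees of the profile.  Built by nesting the
#' consensus clusters, which always form a laminar family.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @return A `phylo` tree in canonical form.
#' @examples
#' strict_consensus(list(parse_newick("((a,b),(c,d));"),
#'                       parse_newick("(((a,b),c),d);")))
#' @export
strict_consensus <- function(profile) {
  profile <- dc_profile(profile)
  phylo_from_nest(strict_consensus_nest(profile))
}

strict_consensus_nest <- function(profile) {
  m <- profile$m
  keys <- consensus_keys(profile, nontrivial = TRUE)
  ids <- lapply(keys, key_to_ids)
  nest_from_laminar(ids, m, profile$taxa)
}

# Assemble a tree from a laminar family of non-trivial clusters (taxon ids)
# over taxa 1..m.  Each cluster's parent is the smallest strictly larger
# cluster containing it (or the root).
nest_from_laminar <- function(ids, m, taxa) {
  sizes <- vapply(ids, length, integer(1))
  o <- order(sizes)
  ids <- ids[o]
  sizes <- sizes[o]
  k <- length(ids)
  # children of each cluster node (k+1 = root); leaves attached likewise
  node_kids <- vector("list", k + 1L)
  parent_of <- function(i) {
    # smallest cluster strictly larger than ids[[i]] containing its taxa;
    # laminarity makes "contains the first taxon and is larger" sufficient
    for (j in seq_len(k)) {
      if (sizes[j] > sizes[i] && ids[[i]][1] %in% ids[[j]]) return(j)
    }
    k + 1L
  }
  leaf_parent <- function(tx) {
    for (j in seq_len(k)) {
      if (tx %in% ids[[j]]) return(j)
    }
    k + 1L
  }
  if (k > 0L) {
    for (i in seq_len(k)) {
      p <- parent_of(i)
      node_kids[[p]] <- c(node_kids[[p]], i)
    }
  }
  leaf_home <- vapply(seq_len(m), leaf_parent, integer(1))
  build <- function(j) {
    subs <- lapply(node_kids[[j]], build)
    leaves <- as.list(taxa[which(leaf_home == j)])
    kids <- c(subs, leaves)
    if (length(kids) == 1L) return(kids[[1]])
    kids
  }
  canon_nest(build(k + 1L))
}

#' Pareto check: does a tree contain all consensus clusters?
#'
#' A species tree satisfies the Pareto property on clusters for a profile
#' when every cluster shared by all gene trees is also one of its clusters.
#'
#' @param stree A `phylo` tree over the profile's taxa.
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @return Logical scalar; when `FALSE` the attribute `"missing"` holds the
#'   list of absent consensus clusters.
#' @export
is_pareto <- function(stree, profile) {
  profile <- dc_profile(profile)
  nest <- as_nest(stree)
  if (!setequal(nest_leaves(nest), profile$taxa)) {
    stop("tree leaf set differs from the profile")
  }
  have <- nest_cluster_keys(nest, profile$taxa)
  need <- consensus_keys(profile)
  missing <- setdiff(need, have)
  structure(length(missing) == 0L,
            missing = lapply(missing, function(k) profile$taxa[key_to_ids(k)]))
}
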