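#' Path length between nested clusters
#'
#' Number of edges on the path from `lca(a)` up to `lca(b)` in `phy`,
#' requiring `a` to be a subset of `b` so the two LCAs are comparable.
#'
#' @param phy A `phylo` tree.
#' @param a,b Character vectors of leaf labels with `a` a subset of `b`.
#' @return Non-negative integer edge count.
#' @examples
#' path_length(parse_newick("((a,c),b);"), "a", c("a", "b"))  # 2
#' @export
path_length <- function(phy, a, b) {
  a <- unique(a); b <- unique(b)
  if (!all(a %in% b)) stop("'a' must be a subset of 'b'")
  nest <- as_nest(phy)
  taxa <- sort(nest_leaves(nest))
  miss <- setdiff(b, taxa)
  if (length(miss)) stop("label(s) not in tree: ", paste(miss, collapse = ", "))
  enc <- enc_from_nest(nest, taxa)
  dep <- enc_depths(enc)
  la <- enc_lca(enc, match(a, taxa), dep)
  lb <- enc_lca(enc, match(b, taxa), dep)
  dep[la] - dep[lb]
}

# LCA of taxon ids on an enc
enc_lca <- function(enc, tax_ids, dep = enc_depths(enc)) {
  nodes <- match(tax_ids, enc$leaf)
  v <- nodes[1]
  for (u in nodes[-1]) {
    while (v != u) {
      if (dep[v] > dep[u]) v <- enc$par[v]
      else if (dep[u] > dep[v]) u <- enc$par[u]
      else { v <- enc$par[v]; u <- enc$par[u] }
    }
  }
  v
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every gene-tree node to the least common ancestor, in the species
#' tree, of the taxa below it.  The mapping is monotone: descendants map to
#' descendants.
#'
#' @param gtree,stree `phylo` trees over the same leaf set.
#' @return A data frame with one row per gene-tree node: `node` (ape index in
#'   `gtree`), `image` (ape index in `stree`), and the gene-node cluster as a
#'   `|`-joined label string.
#' @export
lca_mapping <- function(gtree, stree) {
  stopifnot(inherits(gtree, "phylo"), inherits(stree, "phylo"))
  if (!setequal(gtree$tip.label, stree$tip.label)) {
    stop("gene and species tree must share one leaf set")
  }
  n_nodes <- length(gtree$tip.label) + gtree$Nnode
  images <- integer(n_nodes)
  cl <- character(n_nodes)
  for (v in seq_len(n_nodes)) {
    below <- if (v <= length(gtree$tip.label)) gtree$tip.label[v]
             else ape::extract.clade(gtree, v)$tip.label
    images[v] <- tree_lca(stree, below)
    cl[v] <- paste(sort(below), collapse = "|")
  }
  data.frame(node = seq_len(n_nodes), image = images, cluster = cl,
             stringsAsFactors = FALSE)
}

#' Deep coalescence cost of a gene tree against a species tree
#'
#' For every gene-tree edge, the cost is the length of the species-tree path
#' between the LCA images of the edge's endpoints; the total over all edges
#' is the raw deep coalescence cost.  The classical "extra lineages" count
#' equals the raw cost minus `2m - 2` (`m` taxa): embedding a gene tree
#' congruent with the species tree already incurs a path-length sum of
#' `2m - 2`, and every extra lineage adds exactly one edge to one path.
#'
#' @param gtree,stree Rooted binary `phylo` trees over the same leaf set.
#' @return An object of class `dc_cost`: list with `raw` (the path-length
#'   sum), `extra` (extra lineages, `raw - (2m - 2)`), `m`, and `per_edge`
#'   (data frame of per-gene-tree-edge path lengths).
#' @examples
#' dc_cost(parse_newick("((a,b),c);"), parse_newick("((a,c),b);"))
#' @export
dc_cost <- function(gtree, stree) {
  gn <- as_nest(gtree)
  sn <- as_nest(stree)
  if (!nest_is_binary(gn) || !nest_is_binary(sn)) {
    stop("both trees must be binary")
  }
  taxa <- sort(nest_leaves(sn))
  if (!setequal(nest_leaves(gn), taxa)) {
    stop("gene and species tree must share one leaf set")
  }
  ge <- enc_from_nest(gn, taxa)
  se <- enc_from_nest(sn, taxa)
  sdep <- enc_depths(se)
  gdep <- enc_depths(ge)
  # bottom-up LCA images
  nn <- length(ge$par)
  M <- integer(nn)
  for (v in order(gdep, decreasing = TRUE)) {
    if (ge$leaf[v] > 0L) M[v] <- match(ge$leaf[v], se$leaf)
    p <- ge$par[v]
    if (p > 0L) {
      M[p] <- if (M[p] == 0L) M[v] else enc_lca2(se, M[p], M[v], sdep)
    }
  }
  child <- which(ge$par > 0L)
  pl <- sdep[M[child]] - sdep[M[ge$par[child]]]
  cl <- enc_cluster_ids(ge)
  per_edge <- data.frame(
    edge_child_cluster = vapply(cl[child], function(i)
      paste(taxa[i], collapse = "|"), character(1)),
    path_length = pl,
    stringsAsFactors = FALSE
  )
  raw <- sum(pl)
  m <- length(taxa)
  structure(
    list(raw = raw, extra = raw - (2L * m - 2L), m = m, per_edge = per_edge),
    class = "dc_cost"
  )
}

enc_lca2 <- function(enc, v, u, dep) {
  while (v != u) {
    if (dep[v] > dep[u]) v <- enc$par[v]
    else if (dep[u] > dep[v]) u <- enc$par[u]
    else { v <- enc$par[v]; u <- enc$par[u] }
  }
  v
}

#' @export
print.dc_cost <- function(x, ...) {
  cat("Deep coalescence cost (", x$m, " taxa)\n", sep = "")
  cat("  raw path-length sum:", x$raw, "\n")
  cat("  extra lineages:     ", x$extra, "\n")
  invisible(x)
}

#' Independent extra-lineage count (lineage-tracking oracle)
#'
#' Counts deep coalescence events the classical way: the gene tree is
#' embedded in the species tree, the number of gene lineages crossing the top
#' of every species-tree branch is tallied, and each lineage beyond the first
#' on a branch counts as one extra lineage.  Shares no code with [dc_cost()];
#' it exists as an independent check of the path-length formulation.
#'
#' @inheritParams dc_cost
#' @return Non-negative integer.
#' @export
extra_lineages_oracle <- function(gtree, stree) {
  gn <- as_nest(gtree)
  sn <- as_nest(stree)
  if (!nest_is_binary(gn) || !nest_is_binary(sn)) {
    stop("both trees must be binary")
  }
  taxa <- sort(nest_leaves(sn))
  if (!setequal(nest_leaves(gn), taxa)) {
    stop("gene and species tree must share one leaf set")
  }
  se <- enc_from_nest(sn, taxa)
  s_cl <- enc_cluster_ids(se)
  # species node below which a gene node's cluster fits = its LCA image;
  # computed here by direct "smallest containing cluster" search, not by the
  # bottom-up merge used in dc_cost
  image_of <- function(ids) {
    sizes <- vapply(s_cl, length, integer(1))
    cand <- which(vapply(s_cl, function(s) all(ids %in% s), logical(1)))
    cand[which.min(sizes[cand])]
  }
  ge <- enc_from_nest(gn, taxa)
  g_cl <- enc_cluster_ids(ge)
  M <- vapply(g_cl, image_of, integer(1))
  # lineages crossing the top of the branch above species node v: gene edges
  # (u, parent) with image(u) inside v's subtree and image(parent) outside
  below <- function(a, v) {
    while (a != 0L) {
      if (a == v) return(TRUE)
      a <- se$par[a]
    }
    FALSE
  }
  extra <- 0L
  for (v in seq_along(se$par)) {
    if (se$par[v] == 0L) next  # no branch above the stored root
    crossing <- 0L
    for (u in seq_along(ge$par)) {
      p <- ge$par[u]
      if (p == 0L) next
      if (below(M[u], v) && !below(M[p], v)) crossing <- crossing + 1L
    }
    # a branch traversed by no lineage contributes nothing
    if (crossing > 0L) extra <- extra + (crossing - 1L)
  }
  extra
}

#' Aggregated deep coalescence cost of a profile
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param stree A rooted binary species tree over the profile's taxa.
#' @param convention `"extra"` (default) reports extra lineages summed over
#'   gene trees; `"raw"` reports the plain path-length sums.
#' @return An object of class `dc_agg`: list with `raw`, `extra`, `per_tree`
#'   (vector in the requested convention), and `convention`.
#' @export
aggregate_dc_cost <- function(profile, stree, convention = c("extra", "raw")) {
  convention <- match.arg(convention)
  profile <- dc_profile(profile)
  se <- profile_encode(profile, stree)
  if (!nest_is_binary(nest_from_enc(se))) {
    stop("species tree must be binary")
  }
  per_raw <- cpp_profile_costs(profile_gpar(profile), profile_gleaf(profile),
                               se$par, se$leaf)
  offset <- 2L * profile$m - 2L
  per <- if (convention == "extra") per_raw - offset else per_raw
  structure(
    list(
      raw = sum(per_raw),
      extra = sum(per_raw - offset),
      per_tree = per,
      convention = convention
    ),
    class = "dc_agg"
  )
}

#' @export
print.dc_agg <- function(x, ...) {
  cat("Aggregated deep coalescence cost over", length(x$per_tree),
      "gene trees\n")
  cat("  raw:  ", x$raw, "\n")
  cat("  extra:", x$extra, "\n")
  invisible(x)
}

# fast internal aggregate (raw) from a profile and an enc
agg_raw <- function(profile, se) {
  sum(cpp_profile_costs(profile_gpar(profile), profile_gleaf(profile),
                        se$par, se$leaf))
}
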