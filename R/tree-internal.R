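# Internal tree machinery.
#
# Two in-package representations back the exported "phylo" interface:
#   * "nest": a recursive list; a leaf is its label (character scalar), an
#     internal node an unnamed list of >= 2 children.  Used for edits
#     (restriction, regrouping, cutting, refinement).
#   * "enc": a 1-based parent vector plus a leaf->taxon-id vector, the form
#     consumed by the C++ cost kernels.  The stored root (parent 0) is the
#     child of the implicit degree-one root; node depth in the classical
#     convention is therefore stored depth + 1.
# Conversions go through canonical Newick (children ordered by the smallest
# leaf label in their subtree), which also defines tree equality.

nest_is_leaf <- function(x) is.character(x)

nest_leaves <- function(x) {
  if (nest_is_leaf(x)) return(x)
  unlist(lapply(x, nest_leaves), use.names = FALSE)
}

nest_n_leaves <- function(x) {
  if (nest_is_leaf(x)) return(1L)
  sum(vapply(x, nest_n_leaves, integer(1)))
}

# canonical form: children sorted (radix) by the smallest leaf label below
canon_nest <- function(x) canon_nest_rec(x)$t

canon_nest_rec <- function(x) {
  if (nest_is_leaf(x)) return(list(min = x, t = x))
  ks <- lapply(x, canon_nest_rec)
  o <- order(vapply(ks, `[[`, character(1), "min"), method = "radix")
  ks <- ks[o]
  list(min = ks[[1]]$min, t = lapply(ks, `[[`, "t"))
}

nwk_rec <- function(x) {
  if (nest_is_leaf(x)) return(x)
  paste0("(", paste(vapply(x, nwk_rec, character(1)), collapse = ","), ")")
}

# canonical Newick string of a nest
nest_newick <- function(x) paste0(nwk_rec(canon_nest(x)), ";")

nest_from_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  ntip <- length(phy$tip.label)
  if (ntip == 1L) return(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    lapply(kids[[as.character(v)]], build)
  }
  build(ntip + 1L)
}

phylo_from_nest <- function(x) {
  ape::read.tree(text = nest_newick(x))
}

# Coerce a user-supplied tree to nest: phylo or Newick string.
as_nest <- function(x) {
  if (inherits(x, "phylo")) return(nest_from_phylo(x))
  if (is.character(x) && length(x) == 1L) {
    return(nest_from_phylo(parse_newick(x)))
  }
  stop("cannot interpret object of class '", class(x)[1], "' as a tree")
}

# enc: list(par = integer parent vector (0 = stored root), leaf = integer
# taxon ids (0 = internal), taxa = character vector mapping id -> label)
enc_from_nest <- function(x, taxa) {
  n_nodes <- count_nodes(x)
  par <- integer(n_nodes)
  leaf <- integer(n_nodes)
  k <- 0L
  rec <- function(node, parent) {
    k <<- k + 1L
    id <- k
    par[id] <<- parent
    if (nest_is_leaf(node)) {
      tx <- match(node, taxa)
      if (is.na(tx)) stop("leaf label '", node, "' not in the taxon set")
      leaf[id] <<- tx
    } else {
      for (ch in node) rec(ch, id)
    }
    id
  }
  rec(x, 0L)
  list(par = par, leaf = leaf, taxa = taxa)
}

count_nodes <- function(x) {
  if (nest_is_leaf(x)) return(1L)
  1L + sum(vapply(x, count_nodes, integer(1)))
}

enc_children <- function(enc) {
  nn <- length(enc$par)
  kids <- vector("list", nn)
  for (i in seq_len(nn)) {
    p <- enc$par[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

enc_root <- function(enc) which(enc$par == 0L)

nest_from_enc <- function(enc) {
  kids <- enc_children(enc)
  build <- function(v) {
    if (enc$leaf[v] > 0L) return(enc$taxa[enc$leaf[v]])
    lapply(kids[[v]], build)
  }
  build(enc_root(enc))
}

# depth of every node from the stored root (root = 0)
enc_depths <- function(enc) {
  nn <- length(enc$par)
  dep <- integer(nn)
  dep[enc$par == 0L] <- 0L
  todo <- which(enc$par != 0L)
  # parents always created before children by enc_from_nest, but recompute
  # generically by repeated passes
  done <- enc$par == 0L
  while (length(todo)) {
    ready <- todo[done[enc$par[todo]]]
    if (!length(ready)) stop("cyclic parent vector")
    dep[ready] <- dep[enc$par[ready]] + 1L
    done[ready] <- TRUE
    todo <- setdiff(todo, ready)
  }
  dep
}

# leaf taxon ids below every node
enc_cluster_ids <- function(enc) {
  nn <- length(enc$par)
  dep <- enc_depths(enc)
  cl <- vector("list", nn)
  for (v in order(dep, decreasing = TRUE)) {
    if (enc$leaf[v] > 0L) cl[[v]] <- enc$leaf[v]
    if (enc$par[v] > 0L) {
      p <- enc$par[v]
      cl[[p]] <- c(cl[[p]], cl[[v]])
    }
  }
  lapply(cl, sort.int)
}

cluster_key <- function(ids) paste(ids, collapse = "\r")

# cluster key set of a nest, given the taxon ordering
nest_cluster_keys <- function(x, taxa, nontrivial = FALSE) {
  keys <- character(0)
  m <- length(taxa)
  rec <- function(node) {
    if (nest_is_leaf(node)) return(match(node, taxa))
    ids <- sort.int(unlist(lapply(node, rec), use.names = FALSE))
    keys[[length(keys) + 1L]] <<- cluster_key(ids)
    ids
  }
  all <- rec(x)
  if (!nontrivial) {
    keys <- c(keys, vapply(all, cluster_key, character(1)))
  } else {
    keys <- setdiff(keys, cluster_key(seq_len(m)))
  }
  unique(keys)
}

key_to_ids <- function(key) as.integer(strsplit(key, "\r", fixed = TRUE)[[1]])

# restriction T|X on a nest: drop leaves outside `keep`, suppress resulting
# degree-two nodes; NULL when nothing is kept
nest_restrict <- function(x, keep) {
  if (nest_is_leaf(x)) {
    if (x %in% keep) return(x)
    return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(x, nest_restrict, keep = keep))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1]])
  kids
}

# uniform random binary tree over `labels` by sequential insertion on a
# uniformly chosen edge (including the implicit root edge); consumes the
# R RNG stream
rtopology_nest <- function(labels) {
  m <- length(labels)
  if (m < 1L) stop("need at least one label")
  if (m == 1L) return(labels)
  labels <- sample(labels)
  cur <- list(labels[1], labels[2])
  if (m == 2L) return(cur)
  for (j in 3:m) {
    # edges = one per node (edge to its parent; root node = implicit root edge)
    n_edges <- 2L * (j - 1L) - 1L
    e <- sample.int(n_edges, 1L)
    cur <- insert_at_edge(cur, e, labels[j])$t
  }
  cur
}

# preorder edge numbering: node visited e-th gets the new leaf attached above
insert_at_edge <- function(x, e, lab) {
  # returns list(t = new tree or original, k = edges consumed)
  if (e == 1L) return(list(t = list(x, lab), k = 1L))
  if (nest_is_leaf(x)) return(list(t = x, k = 1L))
  k <- 1L
  kids <- x
  for (i in seq_along(kids)) {
    r <- insert_at_edge(kids[[i]], e - k, lab)
    k <- k + r$k
    if (!identical(r$t, kids[[i]])) {
      kids[[i]] <- r$t
      return(list(t = kids, k = k))
    }
  }
  list(t = kids, k = k)
}
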