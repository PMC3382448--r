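# shared helpers: small-tree shorthand and random-instance generators

nt <- function(s) parse_newick(s)
nwk <- function(phy) write_newick(phy)

# random profile of n binary trees over the first m letters
rand_profile <- function(n, m, labels = letters[seq_len(m)]) {
  dc_profile(lapply(seq_len(n), function(i) random_binary_tree(labels)))
}

# random profile guaranteed to share the non-trivial cluster `cl`: every tree
# grafts a random subtree over `cl` onto a random tree over the rest
rand_profile_with_cluster <- function(n, labels, cl) {
  rest <- setdiff(labels, cl)
  trees <- lapply(seq_len(n), function(i) {
    outer_labels <- c(rest, cl[1])
    big <- deepcoal:::rtopology_nest(outer_labels)
    small <- deepcoal:::rtopology_nest(cl)
    subst <- function(x) {
      if (is.character(x)) {
        if (x == cl[1]) return(small)
        return(x)
      }
      lapply(x, subst)
    }
    deepcoal:::phylo_from_nest(subst(big))
  })
  dc_profile(trees)
}

# a candidate guaranteed to miss at least one consensus cluster of `profile`
rand_nonpareto_candidate <- function(profile, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    cand <- random_binary_tree(profile$taxa)
    if (!isTRUE(is_pareto(cand, profile))) return(cand)
  }
  stop("could not draw a non-Pareto candidate")
}
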