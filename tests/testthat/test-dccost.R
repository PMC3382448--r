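test_that("path_length counts edges between nested LCAs", {
  expect_equal(path_length(nt("((a,c),b);"), "a", c("a", "b")), 2L)
  expect_equal(path_length(nt("((a,b),c);"), "a", c("a", "b")), 1L)
  expect_equal(path_length(nt("((a,b),c);"), c("a", "b"), c("a", "b")), 0L)
  expect_error(path_length(nt("((a,b),c);"), "c", c("a", "b")), "subset")
})

test_that("LCA mapping sends leaves to leaves and is monotone", {
  g <- nt("((a,b),c);")
  s <- nt("((a,c),b);")
  mp <- lca_mapping(g, s)
  # the ab-node of the gene tree maps to the species root (spans a,b,c)
  ab <- mp$image[mp$cluster == "a|b"]
  expect_identical(ab, ape::getMRCA(s, c("a", "b", "c")))
  # leaves map to same-label leaves
  for (lab in c("a", "b", "c")) {
    expect_identical(s$tip.label[mp$image[mp$cluster == lab]], lab)
  }
  # congruent trees: every node maps to the node with the same cluster
  mp2 <- lca_mapping(g, g)
  for (i in seq_len(nrow(mp2))) {
    below <- if (mp2$image[i] <= 3) g$tip.label[mp2$image[i]]
      else sort(ape::extract.clade(g, mp2$image[i])$tip.label)
    expect_identical(paste(below, collapse = "|"), mp2$cluster[i])
  }
})

test_that("deep coalescence cost matches the hand-traced cases", {
  x <- dc_cost(nt("((a,b),c);"), nt("((a,b),c);"))
  expect_equal(x$raw, 4L)
  expect_equal(x$extra, 0L)
  y <- dc_cost(nt("((a,b),c);"), nt("((a,c),b);"))
  expect_equal(y$raw, 5L)
  expect_equal(y$extra, 1L)
  expect_setequal(y$per_edge$path_length, c(2L, 1L, 0L, 2L, 0L))
  expect_equal(sum(y$per_edge$path_length), y$raw)
  expect_equal(dc_cost(nt("(((a,b),c),d);"), nt("((a,b),(c,d));"))$extra, 1L)
  expect_error(dc_cost(nt("(a,b,c);"), nt("((a,b),c);")), "binary")
})

test_that("extra lineages equal the raw cost minus 2m-2 (lineage-count oracle)", {
  # exhaustive: all ordered pairs of 4-taxon topologies
  top4 <- enumerate_rooted_binary(letters[1:4])
  for (ts in top4) {
    for (ss in top4) {
      t <- nt(ts); s <- nt(ss)
      expect_identical(extra_lineages_oracle(t, s), dc_cost(t, s)$extra)
    }
  }
  # random larger pairs
  set.seed(21)
  for (i in 1:60) {
    m <- sample(5:10, 1)
    t <- random_binary_tree(letters[1:m])
    s <- random_binary_tree(letters[1:m])
    expect_identical(extra_lineages_oracle(t, s), dc_cost(t, s)$extra)
  }
})

test_that("congruent cost is 2m-2 and zero extra lineages", {
  set.seed(31)
  for (m in c(3, 5, 8, 10)) {
    t <- random_binary_tree(letters[1:m])
    x <- dc_cost(t, t)
    expect_equal(x$raw, 2L * m - 2L)
    expect_equal(x$extra, 0L)
  }
})

test_that("the cost is not symmetric in its arguments", {
  top4 <- enumerate_rooted_binary(letters[1:4])
  asym <- FALSE
  for (ts in top4) {
    for (ss in top4) {
      if (dc_cost(nt(ts), nt(ss))$raw != dc_cost(nt(ss), nt(ts))$raw) {
        asym <- TRUE
      }
    }
  }
  expect_true(asym)
})

test_that("materialising a degree-one root or degree-two gene nodes changes nothing", {
  set.seed(41)
  for (i in 1:20) {
    m <- sample(4:8, 1)
    taxa <- letters[1:m]
    t <- deepcoal:::enc_from_nest(deepcoal:::rtopology_nest(taxa), taxa)
    s <- deepcoal:::enc_from_nest(deepcoal:::rtopology_nest(taxa), taxa)
    base <- deepcoal:::cpp_dc_raw(t$par, t$leaf, s$par, s$leaf)
    # explicit degree-one root on both trees
    add_root <- function(e) {
      nn <- length(e$par)
      root <- which(e$par == 0L)
      par <- c(e$par, 0L)
      par[root] <- nn + 1L
      list(par = par, leaf = c(e$leaf, 0L))
    }
    t2 <- add_root(t); s2 <- add_root(s)
    expect_identical(deepcoal:::cpp_dc_raw(t2$par, t2$leaf, s2$par, s2$leaf),
                     base)
    # a degree-two node spliced into a random gene-tree edge
    v <- sample(which(t$par != 0L), 1)
    par <- c(t$par, t$par[v])
    par[v] <- length(t$par) + 1L
    expect_identical(deepcoal:::cpp_dc_raw(par, c(t$leaf, 0L), s$par, s$leaf),
                     base)
  }
})

test_that("aggregation sums per-tree costs in both conventions", {
  p <- dc_profile(list(nt("((a,b),c);"), nt("((a,b),c);")))
  a <- aggregate_dc_cost(p, nt("((a,c),b);"))
  expect_equal(a$raw, 10L)
  expect_equal(a$extra, 2L)
  expect_equal(a$per_tree, c(1L, 1L))  # extra convention by default
  expect_equal(aggregate_dc_cost(p, nt("((a,c),b);"), "raw")$per_tree,
               c(5L, 5L))
  # congruent profile scores twice the congruent cost
  t <- nt("((a,b),(c,d));")
  p2 <- dc_profile(list(t, t))
  expect_equal(aggregate_dc_cost(p2, t)$raw, 2L * (2L * 4L - 2L))
  # single-tree instance equals dc_cost
  p3 <- dc_profile(list(nt("((a,b),c);")))
  expect_equal(aggregate_dc_cost(p3, nt("((a,c),b);"))$raw,
               dc_cost(nt("((a,b),c);"), nt("((a,c),b);"))$raw)
})
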