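test_that("Newick parsing validates labels and shape", {
  t1 <- nt("((a,b),c);")
  expect_s3_class(t1, "phylo")
  expect_setequal(t1$tip.label, c("a", "b", "c"))
  star <- nt("(a,b,c);")
  expect_equal(star$Nnode, 1L)
  expect_length(tree_clusters(star, nontrivial = TRUE), 0L)
  expect_error(parse_newick("((a,a),b);"), "duplicate")
  expect_error(parse_newick("((a,b"), "malformed")
})

test_that("canonical serialisation is order-invariant and round-trips", {
  expect_identical(nwk(nt("(c,a,b);")), "(a,b,c);")
  expect_identical(nwk(nt("((b,a),c);")), nwk(nt("(c,(a,b));")))
  for (i in 1:20) {
    set.seed(100 + i)
    t <- random_binary_tree(letters[1:7])
    expect_identical(nwk(parse_newick(nwk(t))), nwk(t))
  }
})

test_that("clusters enumerate every node's leaf set", {
  cl <- tree_clusters(nt("((a,b),c);"))
  expect_setequal(
    vapply(cl, paste, character(1), collapse = ","),
    c("a", "b", "c", "a,b", "a,b,c")
  )
  expect_length(tree_clusters(nt("((a,b),(c,d));")), 7L)
  # binary tree on m leaves has 2m-1 clusters
  for (m in 4:9) {
    set.seed(m)
    expect_length(tree_clusters(random_binary_tree(letters[1:m])), 2L * m - 1L)
  }
})

test_that("restriction suppresses degree-two nodes and commutes with clusters", {
  expect_identical(nwk(restrict_tree(nt("((a,b),(c,d));"), c("a", "c"))),
                   "(a,c);")
  expect_identical(nwk(restrict_tree(nt("((a,b),c);"), c("a", "b"))), "(a,b);")
  set.seed(7)
  for (i in 1:15) {
    m <- sample(5:10, 1)
    t <- random_binary_tree(letters[1:m])
    expect_identical(nwk(restrict_tree(t, letters[1:m])), nwk(t))
    x <- sample(letters[1:m], sample(2:(m - 1), 1))
    r <- restrict_tree(t, x)
    got <- vapply(tree_clusters(r), paste, character(1), collapse = ",")
    want <- unique(Filter(nzchar, vapply(tree_clusters(t), function(cl)
      paste(intersect(cl, x), collapse = ","), character(1))))
    expect_setequal(got, want)
  }
})

test_that("induced subtree exposes degree-two nodes whose suppression gives the restriction", {
  r <- induced_subtree(nt("((a,b),(c,d));"), c("b", "d"))
  expect_identical(r$degree2_depths, c(2L, 2L))
  expect_length(induced_subtree(nt("((a,b),c);"), c("b", "c"))$degree2_depths,
                1L)
  expect_error(induced_subtree(nt("((a,b),c);"), character(0)), "non-empty")
  expect_error(induced_subtree(nt("((a,b),c);"), c("a", "b", "c")), "proper")

  collapse1 <- function(x) {
    if (is.character(x)) return(x)
    kids <- lapply(x, collapse1)
    if (length(kids) == 1L) return(kids[[1]])
    kids
  }
  set.seed(11)
  for (i in 1:15) {
    m <- sample(5:9, 1)
    t <- random_binary_tree(letters[1:m])
    x <- sample(letters[1:m], sample(2:(m - 1), 1))
    ind <- induced_subtree(t, x)
    # a non-trivial split always leaves at least one degree-two node
    expect_gt(length(ind$degree2_depths), 0L)
    sup <- deepcoal:::phylo_from_nest(
      collapse1(deepcoal:::nest_from_phylo(ind$tree))
    )
    expect_identical(nwk(sup), nwk(restrict_tree(t, x)))
  }
})

test_that("refines is a partial order realised by cluster containment", {
  expect_true(refines(nt("((a,b),(c,d));"), nt("((a,b),c,d);")))
  expect_false(refines(nt("((a,c),(b,d));"), nt("((a,b),c,d);")))
  set.seed(5)
  for (i in 1:10) {
    t <- random_binary_tree(letters[1:6])
    expect_true(refines(t, t))  # reflexive
    s <- random_binary_tree(letters[1:6])
    # antisymmetry on canonical trees
    if (refines(t, s) && refines(s, t)) expect_identical(nwk(t), nwk(s))
  }
  # transitivity through a chain: binary refinement of a star refines it
  h <- nt("(a,b,c,d,e);")
  set.seed(6)
  t <- random_refinement(h)
  expect_true(refines(t, h))
})

test_that("profiles are validated for shape and shared leaf set", {
  p <- dc_profile(list(nt("((a,b),c);"), nt("((a,c),b);")))
  expect_identical(p$taxa, c("a", "b", "c"))
  expect_output(print(p), "2 binary trees")
  expect_error(dc_profile(list(nt("((a,b),c);"), nt("((a,b),d);"))),
               "different leaf set")
  expect_error(dc_profile(list(nt("(a,b,c);"))), "not binary")
  expect_error(dc_profile(list()), "at least one")
})

test_that("tree_lca matches definition on the worked cases", {
  t <- nt("((a,b),c);")
  expect_identical(tree_lca(t, c("a", "b")), ape::getMRCA(t, c("a", "b")))
  expect_identical(tree_lca(t, c("a", "c")), 4L)  # root of the 3-leaf tree
  expect_identical(tree_lca(t, "a"), which(t$tip.label == "a"))
  expect_error(tree_lca(t, "z"), "not in tree")
})
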