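test_that("cut collapses consensus child clusters to atomic leaves", {
  H <- nt("((a,b),c,d);")
  h <- tree_lca(H, letters[1:4])
  ct <- cut_tree(H, h, nt("((a,b),(c,d));"))
  expect_identical(nwk(ct$tree), "(c01,(c02,c03));")
  expect_identical(ct$sets$c01, c("a", "b"))
  ct2 <- cut_tree(H, h, nt("(((a,b),c),d);"))
  expect_identical(nwk(ct2$tree), "((c01,c02),c03);")
  # a two-child node cuts to a cherry
  h2 <- tree_lca(H, c("a", "b"))
  ct3 <- cut_tree(H, h2, nt("((a,b),(c,d));"))
  expect_identical(nwk(ct3$tree), "(c01,c02);")
  expect_error(cut_tree(H, h, nt("((a,c),(b,d));")), "refine")
  expect_error(cut_tree(H, 2L, nt("((a,b),(c,d));")), "internal")
})

test_that("cut_instance requires the consensus and aligns atom leaf sets", {
  p <- dc_profile(list(nt("((a,b),(c,d));"), nt("(((a,b),c),d);")))
  H <- strict_consensus(p)
  ci <- cut_instance(p, H, tree_lca(H, letters[1:4]))
  expect_equal(ci$profile$n, 2L)
  expect_setequal(ci$profile$taxa, c("c01", "c02", "c03"))
  expect_setequal(vapply(ci$profile$trees, nwk, character(1)),
                  c("(c01,(c02,c03));", "((c01,c02),c03);"))
  # a tree lacking one child cluster is rejected
  bad <- dc_profile(list(nt("((a,b),(c,d));"), nt("((a,c),(b,d));")))
  expect_error(cut_instance(bad, H, tree_lca(H, letters[1:4])),
               "not the strict consensus")
  # identical profile: all cut trees identical
  t <- nt("(((a,b),c),(d,e));")
  p2 <- dc_profile(list(t, t))
  H2 <- strict_consensus(p2)
  ci2 <- cut_instance(p2, H2, tree_lca(H2, c("a", "b", "c")))
  expect_identical(nwk(ci2$profile$trees[[1]]), nwk(ci2$profile$trees[[2]]))
})

test_that("divide and conquer with the exact sub-solver attains the global optimum", {
  p <- dc_profile(list(nt("((a,b),(c,d));"), nt("(((a,b),c),d);")))
  r <- dc_consensus_method(p, solver = "exact")
  expect_equal(r$score_extra, 1)
  expect_true(nwk(r$tree) %in% c("((a,b),(c,d));", "(((a,b),c),d);"))
  # consensus already binary: returned unchanged
  t <- nt("((a,b),(c,d));")
  expect_identical(nwk(dc_consensus_method(dc_profile(list(t, t)))$tree),
                   nwk(t))
  set.seed(23)
  for (i in 1:20) {
    m <- sample(4:7, 1)
    p <- rand_profile(sample(c(2, 3, 5), 1), m)
    r <- dc_consensus_method(p, solver = "exact")
    ex <- exact_solve(p)
    expect_equal(r$score_raw, ex$score_raw)
    expect_true(as.logical(is_pareto(r$tree, p)))
  }
})

test_that("cutting a global optimum at a consensus node is optimal for the cut instance", {
  set.seed(24)
  for (i in 1:8) {
    m <- sample(5:6, 1)
    p <- rand_profile_with_cluster(sample(2:3, 1), letters[1:m],
                                   sample(letters[1:m], 2))
    H <- strict_consensus(p)
    ex <- exact_solve(p)
    ntip <- length(H$tip.label)
    internal <- ntip + seq_len(H$Nnode)
    for (S in ex$trees) {
      for (h in internal) {
        ci <- cut_instance(p, H, h)
        cutS <- cut_tree(H, h, S)
        sub_ex <- exact_solve(ci$profile)
        expect_equal(aggregate_dc_cost(ci$profile, cutS$tree)$raw,
                     sub_ex$score_raw)
      }
    }
  }
})

test_that("subproblem processing order does not change the result", {
  set.seed(25)
  p <- rand_profile(3, 7)
  r1 <- dc_consensus_method(p, solver = "exact")
  k <- nrow(r1$subproblems)
  for (i in 1:3) {
    r2 <- dc_consensus_method(p, solver = "exact", node_order = sample(k))
    expect_identical(nwk(r2$tree), nwk(r1$tree))
  }
})

test_that("the sub-solver dispatch honours the exact-size threshold", {
  set.seed(26)
  p <- rand_profile(3, 7)  # trivial consensus: one 7-leaf subproblem
  r <- dc_consensus_method(p, solver = "auto", exact_threshold = 4L,
                           restarts = 2)
  expect_true(all(r$subproblems$solver[r$subproblems$size > 4] == "spr"))
  r2 <- dc_consensus_method(p, solver = "auto", exact_threshold = 8L)
  expect_true(all(r2$subproblems$solver == "exact"))
  expect_equal(r2$score_raw, exact_solve(p)$score_raw)
  # a custom sub-solver function is honoured
  r3 <- dc_consensus_method(p, solver = function(sub) exact_solve(sub)$trees[[1]])
  expect_equal(r3$score_raw, exact_solve(p)$score_raw)
})
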