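test_that("regroup attaches the cluster subtree and suppresses degree-two nodes", {
  s <- nt("((a,b),(c,d));")
  r1 <- regroup(s, c("a", "c"), attach = 1)
  r2 <- regroup(s, c("a", "c"), attach = 2)
  expect_setequal(c(nwk(r1), nwk(r2)),
                  c("(((a,c),b),d);", "(((a,c),d),b);"))
  expect_error(regroup(s, "a"), "non-trivial")
  expect_error(regroup(s, letters[1:4]), "non-trivial")
  # postconditions on random cases: binary, leaf-preserving, contains x
  set.seed(12)
  for (i in 1:20) {
    m <- sample(5:9, 1)
    t <- random_binary_tree(letters[1:m])
    x <- sample(letters[1:m], sample(2:(m - 1), 1))
    r <- regroup(t, x, attach = 1)
    expect_setequal(r$tip.label, letters[1:m])
    expect_true(ape::is.binary(r))
    expect_true(any(vapply(tree_clusters(r), setequal, logical(1), x)))
  }
})

test_that("shallowest regrouping returns one tree per shallowest degree-two node", {
  out <- shallowest_regroup(nt("((a,b),(c,d));"), c("a", "c"))
  expect_length(out, 2L)  # both degree-two nodes sit at equal depth
  out2 <- shallowest_regroup(nt("(((a,b),c),d);"), c("b", "c"))
  expect_length(out2, 1L)
  expect_identical(nwk(out2[[1]]), "((a,(b,c)),d);")
  expect_error(shallowest_regroup(nt("((a,b),c);"), c("a", "b")),
               "already present")
  # |output| always equals the number of shallowest degree-two nodes
  set.seed(13)
  for (i in 1:15) {
    m <- sample(5:8, 1)
    t <- random_binary_tree(letters[1:m])
    x <- sample(letters[1:m], sample(2:(m - 1), 1))
    keys <- vapply(tree_clusters(t), paste, character(1), collapse = ",")
    if (paste(sort(x), collapse = ",") %in% keys) next
    deps <- induced_subtree(t, setdiff(letters[1:m], x))$degree2_depths
    expect_length(shallowest_regroup(t, x), sum(deps == min(deps)))
  }
})

test_that("repair adds the consensus clusters and strictly lowers every gene cost", {
  p <- dc_profile(list(nt("((a,b),c);"), nt("((a,b),c);")))
  r <- improve_candidate(p, nt("((a,c),b);"))
  expect_identical(nwk(r$tree), "((a,b),c);")
  expect_equal(r$cost_before, 10)
  expect_equal(r$cost_after, 8)
  # no-op branch
  r0 <- improve_candidate(p, nt("((a,b),c);"))
  expect_false(r0$repaired)
  expect_equal(r0$cost_before, r0$cost_after)
  expect_identical(nwk(r0$tree), "((a,b),c);")

  set.seed(14)
  for (i in 1:25) {
    m <- sample(5:8, 1)
    cl <- sample(letters[1:m], sample(2:3, 1))
    p <- rand_profile_with_cluster(sample(2:4, 1), letters[1:m], cl)
    cand <- rand_nonpareto_candidate(p)
    r <- improve_candidate(p, cand)
    expect_true(as.logical(is_pareto(r$tree, p)))
    expect_lt(r$cost_after, r$cost_before)
    # per-step, per-gene-tree strict decrease (the repair guarantee)
    for (st in r$steps) {
      expect_true(all(st$costs_after < st$costs_before))
    }
  }
})

test_that("every cluster processing order yields a Pareto tree at non-increasing cost", {
  set.seed(15)
  t0 <- random_binary_tree(letters[1:7])
  p <- dc_profile(list(t0, t0, t0))  # consensus = t0: five non-trivial clusters
  cand <- rand_nonpareto_candidate(p)
  k <- length(consensus_clusters(p, nontrivial = TRUE))
  expect_equal(k, 5L)
  orders <- list(seq_len(k), rev(seq_len(k)), sample(k))
  for (o in orders) {
    r <- improve_candidate(p, cand, cluster_order = o)
    expect_true(as.logical(is_pareto(r$tree, p)))
    expect_lte(r$cost_after, r$cost_before)
  }
})

test_that("previously regrouped clusters are retained throughout the repair", {
  set.seed(16)
  for (i in 1:10) {
    m <- 8
    p <- rand_profile_with_cluster(3, letters[1:m], c("a", "c", "e"))
    cand <- rand_nonpareto_candidate(p)
    r <- improve_candidate(p, cand)
    seen <- list()
    for (st in r$steps) {
      seen <- c(seen, list(st$cluster))
    }
    final_keys <- vapply(tree_clusters(r$tree), paste, character(1),
                         collapse = ",")
    for (cl in seen) {
      expect_true(paste(sort(cl), collapse = ",") %in% final_keys)
    }
  }
})
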