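# Exact and SPR-heuristic solvers for the aggregated deep coalescence
# objective.  The exact solver enumerates all (2m-3)!! rooted binary
# topologies; the heuristic is a steepest-descent hill climb over the rooted
# SPR neighbourhood.

# cache of enumeration matrices, one per m
.enum_cache <- new.env(parent = emptyenv())

# Matrix of parent vectors of all rooted binary topologies over m labelled
# leaves.  Nodes: leaves 1..m, internals m+1..2m-1.  Built by inserting leaf
# j on every edge (including the implicit root edge) of every (j-1)-leaf
# tree, using internal node m+j-1 for the new attachment node.
enum_par_matrix <- function(m) {
  stopifnot(m >= 2L, m <= 9L)
  key <- as.character(m)
  if (!is.null(.enum_cache[[key]])) return(.enum_cache[[key]])
  nn <- 2L * m - 1L
  cur <- matrix(0L, nrow = 1L, ncol = nn)
  cur[1, 1] <- m + 1L  # leaves 1,2 under internal m+1 (the 2-leaf root)
  cur[1, 2] <- m + 1L
  if (m > 2L) {
    for (j in 3:m) {
      newint <- m + j - 1L
      live <- c(seq_len(j - 1L), m + seq_len(j - 2L))  # nodes present so far
      nxt <- matrix(0L, nrow = nrow(cur) * length(live), ncol = nn)
      r <- 0L
      for (i in seq_len(nrow(cur))) {
        base <- cur[i, ]
        for (u in live) {
          r <- r + 1L
          row <- base
          row[newint] <- row[u]  # may be 0: insertion on the root edge
          row[u] <- newint
          row[j] <- newint
          nxt[r, ] <- row
        }
      }
      cur <- nxt
    }
  }
  .enum_cache[[key]] <- cur
  cur
}

enc_from_enum_row <- function(row, taxa) {
  m <- length(taxa)
  list(par = as.integer(row), leaf = c(seq_len(m), integer(m - 1L)),
       taxa = taxa)
}

#' Enumerate all rooted binary topologies over a label set
#'
#' There are `(2m-3)!!` rooted binary topologies on `m` labelled leaves; the
#' enumeration is exhaustive and duplicate-free.
#'
#' @param labels Character vector of 2 to 9 leaf labels.
#' @param as `"newick"` (canonical strings, default) or `"phylo"`.
#' @return A character vector or list of `phylo` trees.
#' @examples
#' enumerate_rooted_binary(c("a", "b", "c"))
#' @export
enumerate_rooted_binary <- function(labels, as = c("newick", "phylo")) {
  as <- match.arg(as)
  labels <- unique(labels)
  m <- length(labels)
  if (m < 2L || m > 9L) stop("between 2 and 9 labels are supported")
  taxa <- sort(labels)
  mat <- enum_par_matrix(m)
  out <- vapply(seq_len(nrow(mat)), function(i) {
    nest_newick(nest_from_enc(enc_from_enum_row(mat[i, ], taxa)))
  }, character(1))
  if (as == "newick") out else lapply(out, function(s) parse_newick(s))
}

#' Exact deep coalescence solver by exhaustive enumeration
#'
#' Scores every rooted binary topology over the profile's taxa and returns
#' the complete set of optima.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param guard Refuse instances with more taxa than this (enumeration is
#'   `(2m-3)!!`; the practical ceiling for exact solutions is 8 taxa).
#' @return An object of class `dc_solution`: list with `trees` (all optima,
#'   canonical `phylo`), `score_raw`, `score_extra`, `method`, and
#'   `diagnostics` (`n_candidates`).
#' @export
exact_solve <- function(profile, guard = 8L) {
  profile <- dc_profile(profile)
  m <- profile$m
  if (m > guard) {
    stop("instance has ", m, " taxa; exact enumeration is guarded at ", guard)
  }
  mat <- enum_par_matrix(m)
  scores <- cpp_score_candidates(mat, m, profile_gpar(profile),
                                 profile_gleaf(profile))
  best <- min(scores)
  idx <- which(scores == best)
  nwks <- sort(vapply(idx, function(i) {
    nest_newick(nest_from_enc(enc_from_enum_row(mat[i, ], profile$taxa)))
  }, character(1)))
  new_solution(
    trees = lapply(nwks, parse_newick),
    score_raw = best,
    n = profile$n, m = m,
    method = "exact",
    diagnostics = list(n_candidates = nrow(mat))
  )
}

new_solution <- function(trees, score_raw, n, m, method, diagnostics) {
  structure(
    list(
      trees = trees,
      score_raw = score_raw,
      score_extra = score_raw - n * (2L * m - 2L),
      method = method,
      diagnostics = diagnostics
    ),
    class = "dc_solution"
  )
}

#' @export
print.dc_solution <- function(x, ...) {
  cat("Deep coalescence solver result (", x$method, ")\n", sep = "")
  cat("  best tree(s):", length(x$trees), "\n")
  cat("  score: raw", x$score_raw, "/ extra lineages", x$score_extra, "\n")
  invisible(x)
}

# apply one rooted SPR move on an enc: prune node u, regraft on the edge
# above node w (R mirror of the C++ construction)
spr_apply <- function(enc, u, w) {
  par <- enc$par
  p <- par[u]
  sib <- setdiff(which(par == p), u)
  par[sib] <- par[p]
  par[p] <- par[w]
  par[w] <- p
  par[u] <- p
  list(par = par, leaf = enc$leaf, taxa = enc$taxa)
}

spr_moves <- function(enc) {
  par <- enc$par
  nn <- length(par)
  root <- which(par == 0L)
  anc <- function(x) {
    out <- integer(0)
    while (x != 0L) { out <- c(out, x); x <- par[x] }
    out
  }
  moves <- list()
  for (u in seq_len(nn)) {
    p <- par[u]
    if (p == 0L) next
    sib <- setdiff(which(par == p), u)
    sub <- which(vapply(seq_len(nn), function(x) u %in% anc(x), logical(1)))
    for (w in seq_len(nn)) {
      if (w %in% sub || w == p || w == sib) next
      moves[[length(moves) + 1L]] <- c(u, w)
    }
  }
  moves
}

#' Rooted SPR neighbourhood of a binary tree
#'
#' All distinct trees reachable by pruning one subtree and regrafting it on
#' any other edge (including the root edge), excluding the tree itself.
#'
#' @param stree A rooted binary `phylo` tree with at least 3 leaves.
#' @return A list of `phylo` trees, duplicate-free under canonical form.
#' @examples
#' length(spr_neighbors(parse_newick("((a,b),c);")))  # 2
#' @export
spr_neighbors <- function(stree) {
  nest <- as_nest(stree)
  if (!nest_is_binary(nest)) stop("tree must be binary")
  taxa <- sort(nest_leaves(nest))
  if (length(taxa) < 3L) stop("SPR needs at least 3 leaves")
  enc <- enc_from_nest(nest, taxa)
  self <- nest_newick(nest)
  nwks <- vapply(spr_moves(enc), function(mv) {
    nest_newick(nest_from_enc(spr_apply(enc, mv[1], mv[2])))
  }, character(1))
  nwks <- setdiff(unique(nwks), self)
  lapply(sort(nwks), parse_newick)
}

#' SPR hill-climbing solver
#'
#' Steepest-descent local search over the rooted SPR neighbourhood of the
#' aggregated deep coalescence cost.  Each restart descends until no
#' neighbour scores strictly better; ties among equally best neighbours are
#' broken by canonical-Newick order, so runs are reproducible given the RNG
#' seed.
#'
#' @param profile A [dc_profile()] (or coercible list of trees).
#' @param start `"consensus-refinement"` (default: a random binary
#'   refinement of the strict consensus, which already contains every
#'   consensus cluster), `"random"` (uniform topology), or a `phylo` tree.
#' @param restarts Number of independent restarts (the best result is kept).
#' @param max_iter Cap on descent steps per restart.
#' @param seed Optional integer; when given, `set.seed(seed)` is applied so
#'   the run is reproducible.
#' @return A `dc_solution` whose `trees` holds the single best local optimum
#'   found; `diagnostics` records iterations, neighbourhood evaluations,
#'   restarts, per-restart scores, and the seed.
#' @export
spr_solve <- function(profile, start = c("consensus-refinement", "random"),
                      restarts = 1L, max_iter = Inf, seed = NULL) {
  profile <- dc_profile(profile)
  if (profile$m < 3L) stop("SPR search needs at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  fixed_start <- NULL
  if (inherits(start, "phylo")) {
    fixed_start <- profile_encode(profile, start)
    if (!nest_is_binary(nest_from_enc(fixed_start))) {
      stop("start tree must be binary")
    }
  } else {
    start <- match.arg(start)
  }
  gpar <- profile_gpar(profile)
  gleaf <- profile_gleaf(profile)
  best <- NULL
  per_restart <- numeric(restarts)
  paths <- vector("list", restarts)
  iters <- 0L
  evals <- 0L
  for (r in seq_len(restarts)) {
    cur <- if (!is.null(fixed_start)) fixed_start
      else if (start == "random") {
        enc_from_nest(rtopology_nest(profile$taxa), profile$taxa)
      } else {
        enc_from_nest(
          random_refinement_nest(strict_consensus_nest(profile)),
          profile$taxa
        )
      }
    cur_score <- sum(cpp_profile_costs(gpar, gleaf, cur$par, cur$leaf))
    path <- cur_score
    it <- 0L
    while (it < max_iter) {
      nb <- cpp_spr_scores(cur$par, cur$leaf, gpar, gleaf)
      evals <- evals + length(nb$score)
      sc <- min(nb$score)
      if (sc >= cur_score) break
      tie <- which(nb$score == sc)
      nwks <- vapply(tie, function(k) {
        nest_newick(nest_from_enc(spr_apply(cur, nb$u[k], nb$w[k])))
      }, character(1))
      pick <- tie[order(nwks, method = "radix")[1]]
      cur <- spr_apply(cur, nb$u[pick], nb$w[pick])
      cur_score <- sc
      path <- c(path, sc)
      it <- it + 1L
    }
    iters <- iters + it
    per_restart[r] <- cur_score
    paths[[r]] <- path
    if (is.null(best) || cur_score < best$score) {
      best <- list(enc = cur, score = cur_score)
    }
  }
  new_solution(
    trees = list(phylo_from_nest(nest_from_enc(best$enc))),
    score_raw = best$score,
    n = profile$n, m = profile$m,
    method = "spr",
    diagnostics = list(iterations = iters, evaluations = evals,
                      restarts = restarts, restart_scores = per_restart,
                      score_paths = paths, seed = seed)
  )
}
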