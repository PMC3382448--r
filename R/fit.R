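#' Fit a minimum deep coalescence species tree
#'
#' The main fitting entry point: given a profile of rooted binary gene trees
#' over one taxon set, estimates the species tree minimising the aggregated
#' deep coalescence cost.
#'
#' Methods: `"divide"` (default) runs the divide-and-conquer search — the
#' strict consensus of the gene trees is computed and each of its
#' multifurcations is refined by an independent subproblem solve (exact up
#' to `exact_threshold` leaves, rooted-SPR hill climbing above), so the fit
#' is guaranteed to contain every cluster shared by all gene trees.
#' `"spr"` is the standalone SPR hill climb over the full tree space, the
#' classical comparator, which carries no such guarantee.  `"exact"`
#' enumerates all rooted binary topologies (practical up to 8 taxa).
#'
#' @param trees Gene trees: a [dc_profile()], `multiPhylo`, list of `phylo`,
#'   or path handled by [read_tree_profile()].
#' @param method `"divide"`, `"spr"`, or `"exact"`.
#' @param exact_threshold Subproblem size up to which `"divide"` solves
#'   exactly.
#' @param restarts Restarts for SPR searches.
#' @param start Start-tree policy for `method = "spr"` (see [spr_solve()]).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `dc_fit` with components `tree` (the fitted
#'   `phylo`), `score_extra` and `score_raw` (aggregated extra-lineage and
#'   raw deep coalescence scores), `per_tree` (per-gene extra lineages),
#'   `pareto` (does the fit contain every consensus cluster?), `method`,
#'   `diagnostics`, and `profile`.
#' @examples
#' p <- dc_profile(list(parse_newick("((a,b),(c,d));"),
#'                      parse_newick("(((a,b),c),d);")))
#' fit <- dc_species_tree(p)
#' fit
#' summary(fit)
#' @export
dc_species_tree <- function(trees,
                            method = c("divide", "spr", "exact"),
                            exact_threshold = 8L, restarts = 1L,
                            start = "consensus-refinement", seed = NULL) {
  method <- match.arg(method)
  if (is.character(trees) && length(trees) == 1L && file.exists(trees)) {
    trees <- read_tree_profile(trees)
  }
  profile <- dc_profile(trees)
  if (!is.null(seed)) set.seed(seed)
  res <- switch(method,
    divide = {
      r <- dc_consensus_method(profile, solver = "auto",
                               exact_threshold = exact_threshold,
                               restarts = restarts)
      list(tree = r$tree, raw = r$score_raw,
           diagnostics = list(subproblems = r$subproblems))
    },
    spr = {
      r <- spr_solve(profile, start = start, restarts = restarts)
      list(tree = r$trees[[1]], raw = r$score_raw, diagnostics = r$diagnostics)
    },
    exact = {
      r <- exact_solve(profile)
      list(tree = r$trees[[1]], raw = r$score_raw,
           diagnostics = c(r$diagnostics, list(n_optima = length(r$trees))))
    }
  )
  offset <- 2L * profile$m - 2L
  per_raw <- cpp_profile_costs(profile_gpar(profile), profile_gleaf(profile),
                               profile_encode(profile, res$tree)$par,
                               profile_encode(profile, res$tree)$leaf)
  structure(
    list(
      tree = res$tree,
      score_raw = res$raw,
      score_extra = res$raw - profile$n * offset,
      per_tree = as.integer(per_raw - offset),
      pareto = as.logical(is_pareto(res$tree, profile)),
      method = method,
      diagnostics = res$diagnostics,
      profile = profile,
      call = match.call()
    ),
    class = "dc_fit"
  )
}

#' @export
print.dc_fit <- function(x, ...) {
  cat("Minimum deep coalescence species tree (method: ", x$method, ")\n",
      sep = "")
  cat("  gene trees: ", x$profile$n, "  taxa: ", x$profile$m, "\n", sep = "")
  cat("  score: ", x$score_extra, " extra lineages (raw ", x$score_raw,
      ")\n", sep = "")
  cat("  contains all consensus clusters: ", x$pareto, "\n", sep = "")
  if (x$profile$m <= 20L) cat("  tree: ", write_newick(x$tree), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dc_fit <- function(object, ...) {
  cc <- consensus_clusters(object$profile, nontrivial = TRUE)
  structure(
    list(
      fit = object,
      n_consensus_clusters = length(cc),
      per_tree = object$per_tree
    ),
    class = "summary.dc_fit"
  )
}

#' @export
print.summary.dc_fit <- function(x, ...) {
  print(x$fit)
  cat("  non-trivial consensus clusters: ", x$n_consensus_clusters, "\n",
      sep = "")
  cat("  per-gene-tree extra lineages:\n")
  print(summary(x$per_tree))
  invisible(x)
}

#' @export
plot.dc_fit <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
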