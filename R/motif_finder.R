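#' Enumerate (alpha, beta)-cliques of a divided network
#'
#' Runs a bounded, pivotless Bron--Kerbosch search over the two-typed,
#' divided network and returns exactly the maximal cliques `S` with
#' `type_count(S, positive) >= alpha` and `type_count(S, negative) <= beta`.
#' Every such clique factors as (organism set) x (COG set) -- each organism
#' contributes its full copy of the module or nothing -- so results are
#' reported as modules: a COG set together with the positive and negative
#' organisms carrying it.
#'
#' Two optional search bounds prune the recursion without changing the
#' output:
#'
#' * the beta bound abandons a branch as soon as the growing clique already
#'   touches more than `beta` negative organisms (type counts only grow
#'   along a branch);
#' * the alpha bound abandons a branch when even the union of the current
#'   clique and all remaining candidates touches fewer than `alpha`
#'   positive organisms.
#'
#' All three `bound_mode`s return identical module sets; tighter modes only
#' visit fewer search-tree nodes.
#'
#' @param network A `divided_network` from [build_divided_network()].
#' @param alpha Minimum number of positive (phenotype-expressing) organisms;
#'   `alpha = 0` with `beta` equal to the number of negative organisms
#'   yields all maximal cliques of the network.
#' @param beta Maximum number of negative organisms.
#' @param bound_mode `"alpha_beta"` (both bounds, default), `"beta_only"`,
#'   or `"none"` (output filter only).
#' @param min_cogs Drop modules with fewer distinct COGs than this
#'   (default 1, i.e. keep everything, including orthology-only
#'   single-COG modules).
#'
#' @return An `ab_modules` tibble in canonical order (COG-set size
#'   descending, then lexicographic COG set, then lexicographic organism
#'   set) with list-columns `cogs` (union of COGs over participants),
#'   `positive_orgs`, `negative_orgs`, `org_cogs` (the exact COG set each
#'   organism contributes), and columns `n_cogs`, `alpha_count`,
#'   `beta_count`, `is_product` (does every participant carry the full COG
#'   set?), `p_value`, `phylo_score` (the last two `NA` until filled by
#'   [clique_significance()] / [add_phylo_scores()]). The number of
#'   search-tree nodes visited is attached as attribute `nodes`.
#'
#' @examples
#' coh <- generate_cohort(cohort_params(
#'   n_pos = 2, n_neg = 1, universe_size = 3, presence_prob = 1,
#'   background_edge_prob = 0, seed = 1,
#'   planted = list(planted_module(c("COG0001", "COG0002"),
#'                                 positive_carriers = c("pos_01", "pos_02")))
#' ))
#' net <- build_divided_network(coh$links, coh$annotations, 800,
#'                              nodes = coh$nodes)
#' enumerate_ab_cliques(net, alpha = 2, beta = 0)
#' @export
enumerate_ab_cliques <- function(network, alpha, beta,
                                 bound_mode = c("alpha_beta", "beta_only",
                                                "none"),
                                 min_cogs = 1L) {
  stopifnot(inherits(network, "divided_network"))
  bound_mode <- match.arg(bound_mode)
  counts <- table(factor(network$organisms$phenotype,
                         c("positive", "negative")))
  check_ab(alpha, beta, counts[["positive"]], counts[["negative"]])

  v <- network$vertices
  org_levels <- network$organisms$organism
  res <- enumerate_ab_cpp(
    network$adj,
    match(v$organism, org_levels),
    network$organisms$phenotype == "positive",
    as.integer(alpha), as.integer(beta),
    switch(bound_mode, none = 0L, beta_only = 1L, alpha_beta = 2L)
  )
  modules <- cliques_to_modules(network, res$cliques)
  modules <- modules[modules$n_cogs >= min_cogs, , drop = FALSE]
  new_ab_modules(modules, alpha = alpha, beta = beta,
                 bound_mode = bound_mode, nodes = res$nodes)
}

# alpha above the positive-organism count is allowed and simply yields an
# empty result; negative or non-integer values are parameter errors
check_ab <- function(alpha, beta, n_pos, n_neg) {
  ok <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 0 && x == floor(x)
  if (!ok(alpha)) abort_param("`alpha` must be a non-negative integer")
  if (!ok(beta)) abort_param("`beta` must be a non-negative integer")
  invisible(TRUE)
}

# vertex-id cliques -> canonical module tibble. A module's `cogs` is the
# union of COGs over the participating organisms; an organism participates
# as soon as it contributes one vertex (the type-count semantics). The
# exact per-organism vertex sets are kept in `org_cogs` -- a maximal
# clique need not be a full organism x COG product when one organism
# carries only part of another's association structure -- and `is_product`
# records whether every participant carries the full COG set.
cliques_to_modules <- function(network, cliques) {
  v <- network$vertices
  pheno <- network$organisms
  rows <- lapply(cliques, function(vids) {
    orgs <- v$organism[vids]
    cogs <- v$cog[vids]
    u_orgs <- sort_c(unique(orgs))
    u_cogs <- sort_c(unique(cogs))
    by_org <- lapply(u_orgs, function(o) sort_c(cogs[orgs == o]))
    names(by_org) <- u_orgs
    ph <- pheno$phenotype[match(u_orgs, pheno$organism)]
    list(
      cogs = u_cogs,
      positive_orgs = u_orgs[ph == "positive"],
      negative_orgs = u_orgs[ph == "negative"],
      org_cogs = by_org,
      is_product = length(vids) == length(u_orgs) * length(u_cogs)
    )
  })
  modules <- tibble(
    cogs = lapply(rows, `[[`, "cogs"),
    positive_orgs = lapply(rows, `[[`, "positive_orgs"),
    negative_orgs = lapply(rows, `[[`, "negative_orgs")
  )
  modules$n_cogs <- vapply(modules$cogs, length, integer(1))
  modules$alpha_count <- vapply(modules$positive_orgs, length, integer(1))
  modules$beta_count <- vapply(modules$negative_orgs, length, integer(1))
  modules$p_value <- NA_real_
  modules$phylo_score <- NA_real_
  modules$org_cogs <- lapply(rows, `[[`, "org_cogs")
  modules$is_product <- vapply(rows, `[[`, logical(1), "is_product")
  canonicalise_modules(modules)
}

# exact clique identity: the full per-organism vertex sets
vertex_set_key <- function(modules) {
  vapply(modules$org_cogs, function(oc) {
    paste(names(oc),
          vapply(oc, paste, character(1), collapse = ","),
          sep = ":", collapse = "|")
  }, character(1))
}

canonicalise_modules <- function(modules) {
  key_cogs <- vapply(modules$cogs, paste, character(1), collapse = ";")
  key_orgs <- vapply(
    seq_len(nrow(modules)),
    function(i) paste(sort_c(c(modules$positive_orgs[[i]],
                               modules$negative_orgs[[i]])), collapse = ";"),
    character(1)
  )
  modules[order_c(-modules$n_cogs, key_cogs, key_orgs,
                  vertex_set_key(modules)), , drop = FALSE]
}

new_ab_modules <- function(modules, ...) {
  out <- as_tibble(modules)
  class(out) <- c("ab_modules", class(tibble()))
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

module_key <- function(modules) vertex_set_key(modules)

#' Exhaustive reference enumeration of (alpha, beta)-cliques
#'
#' Independent oracle for [enumerate_ab_cliques()]: enumerates *all* maximal
#' cliques of the divided network with igraph's unmodified maximal-clique
#' routine, then filters by the (alpha, beta)-criterion. Intended for
#' verification on small networks only; refuses inputs above
#' `max_vertices`.
#'
#' @inheritParams enumerate_ab_cliques
#' @param max_vertices Refusal guard on the exhaustive enumeration
#'   (default 60 vertices).
#' @return An `ab_modules` tibble with the same contract and canonical
#'   order as [enumerate_ab_cliques()].
#' @export
oracle_ab_cliques <- function(network, alpha, beta, max_vertices = 60L,
                              min_cogs = 1L) {
  stopifnot(inherits(network, "divided_network"))
  counts <- table(factor(network$organisms$phenotype,
                         c("positive", "negative")))
  check_ab(alpha, beta, counts[["positive"]], counts[["negative"]])
  n <- nrow(network$vertices)
  if (n > max_vertices) {
    abort(sprintf(
      "oracle refused: %d vertices exceeds the exhaustive guard of %d",
      n, max_vertices
    ), class = "abmotif_size_error")
  }
  if (n == 0) {
    return(new_ab_modules(cliques_to_modules(network, list()),
                          alpha = alpha, beta = beta, bound_mode = "oracle"))
  }
  edges <- unlist(lapply(seq_len(n), function(i) {
    nb <- network$adj[[i]]
    nb <- nb[nb > i]
    rbind(rep(i, length(nb)), nb)
  }))
  if (is.null(edges)) edges <- integer(0)
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, as.integer)
  keep <- vapply(cl, function(vids) {
    type_count(network, vids, "positive") >= alpha &&
      type_count(network, vids, "negative") <= beta
  }, logical(1))
  modules <- cliques_to_modules(network, cl[keep])
  modules <- modules[modules$n_cogs >= min_cogs, , drop = FALSE]
  new_ab_modules(modules, alpha = alpha, beta = beta, bound_mode = "oracle")
}

#' Clique counts over a grid of (alpha, beta) values
#'
#' Counts the (alpha, beta)-cliques for every cell of an alpha x beta grid.
#' All maximal cliques are enumerated once at the loosest setting
#' `(0, n_neg)`; each cell's count then follows by filtering on the cliques'
#' type counts, since a maximal clique satisfies a cell's criterion exactly
#' when `alpha_count >= alpha` and `beta_count <= beta`. Counts are
#' non-increasing in alpha and non-decreasing in beta, with the maximum at
#' `(0, n_neg)` (the all-maximal-cliques setting).
#'
#' @inheritParams enumerate_ab_cliques
#' @param alphas,betas Integer vectors of grid values (defaults: full
#'   feasible ranges).
#' @return An `ab_grid` tibble with columns `alpha`, `beta`, `n_cliques`.
#' @export
scan_parameter_grid <- function(network, alphas = NULL, betas = NULL) {
  stopifnot(inherits(network, "divided_network"))
  counts <- table(factor(network$organisms$phenotype,
                         c("positive", "negative")))
  n_pos <- counts[["positive"]]
  n_neg <- counts[["negative"]]
  alphas <- sort(unique(as.integer(alphas %||% 0:n_pos)))
  betas <- sort(unique(as.integer(betas %||% 0:n_neg)))
  if (any(alphas < 0) || any(betas < 0)) {
    abort_param("grid values must be non-negative")
  }
  all_cliques <- enumerate_ab_cliques(network, 0L, n_neg,
                                      bound_mode = "alpha_beta")
  grid <- tidyr::expand_grid(alpha = alphas, beta = betas)
  grid$n_cliques <- vapply(seq_len(nrow(grid)), function(i) {
    sum(all_cliques$alpha_count >= grid$alpha[i] &
          all_cliques$beta_count <= grid$beta[i])
  }, numeric(1))
  structure(grid, class = c("ab_grid", class(tibble())))
}

#' Compare the three search-bound implementations
#'
#' Runs the enumeration under all three bound modes, asserts that the three
#' module sets are identical, and reports the number of search-tree nodes
#' each mode visited (deterministic) along with wall time (informational
#' only -- never assert on it).
#'
#' @inheritParams enumerate_ab_cliques
#' @return An `ab_benchmark` tibble with columns `bound_mode`, `n_modules`,
#'   `nodes`, `seconds`; the common module set is attached as attribute
#'   `modules`.
#' @export
benchmark_bounds <- function(network, alpha, beta) {
  modes <- c("none", "beta_only", "alpha_beta")
  runs <- lapply(modes, function(m) {
    t0 <- proc.time()[["elapsed"]]
    mods <- enumerate_ab_cliques(network, alpha, beta, bound_mode = m)
    list(modules = mods, nodes = attr(mods, "nodes"),
         seconds = proc.time()[["elapsed"]] - t0)
  })
  keys <- lapply(runs, function(r) module_key(r$modules))
  if (!all(vapply(keys[-1], identical, logical(1), keys[[1]]))) {
    abort("internal error: bound modes disagree on the module set",
          class = "abmotif_internal_error")
  }
  out <- tibble(
    bound_mode = modes,
    n_modules = vapply(runs, function(r) nrow(r$modules), integer(1)),
    nodes = vapply(runs, function(r) r$nodes, numeric(1)),
    seconds = vapply(runs, function(r) r$seconds, numeric(1))
  )
  structure(out, modules = runs[[1]]$modules,
            class = c("ab_benchmark", class(tibble())))
}
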