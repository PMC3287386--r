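# Fixtures and independent oracles shared across the suite. Everything is
# built in code; no data files.

# three-organism toy cohort: A(+) and B(+) each carry the association
# c1--c2 at score 900; C(-) contains only the COG c1 (no edges)
toy_cohort <- function(score_b = 900L) {
  list(
    links = tibble::tibble(
      organism = c("A", "B"),
      node1 = "c1", node2 = "c2",
      combined_score = c(900L, score_b)
    ),
    annotations = tibble::tibble(
      organism = c("A", "B", "C"),
      phenotype = c("positive", "positive", "negative")
    ),
    nodes = tibble::tibble(organism = "C", cog = "c1")
  )
}

toy_network <- function(edge_threshold = 800, score_b = 900L) {
  toy <- toy_cohort(score_b)
  build_divided_network(toy$links, toy$annotations, edge_threshold,
                        nodes = toy$nodes)
}

# single positive organism, complete multipartite network with k parts of
# `part_size` COGs (edges across parts only): 3^k maximal cliques when
# part_size = 3
multipartite_network <- function(k, part_size = 3) {
  cogs <- sprintf("c%02d", seq_len(k * part_size))
  part <- rep(seq_len(k), each = part_size)
  pairs <- t(utils::combn(seq_along(cogs), 2))
  keep <- part[pairs[, 1]] != part[pairs[, 2]]
  links <- tibble::tibble(
    organism = "X",
    node1 = cogs[pairs[keep, 1]],
    node2 = cogs[pairs[keep, 2]],
    combined_score = 900L
  )
  ann <- tibble::tibble(organism = "X", phenotype = "positive")
  build_divided_network(links, ann, 800)
}

# small random cohort for oracle-equivalence style properties:
# <= 6 organisms x <= 8 COGs
random_small_params <- function(seed) {
  set.seed(seed)
  n_pos <- sample(1:4, 1)
  n_neg <- sample(0:2, 1)
  cohort_params(
    n_pos = n_pos, n_neg = n_neg,
    universe_size = sample(4:8, 1),
    presence_prob = runif(1, 0.5, 0.9),
    background_edge_prob = runif(1, 0.1, 0.4),
    background_score_range = c(400L, 999L),
    seed = seed
  )
}

random_small_network <- function(seed, edge_threshold = 700) {
  coh <- generate_cohort(random_small_params(seed))
  build_divided_network(coh$links, coh$annotations, edge_threshold,
                        nodes = coh$nodes)
}

# canonical identity of a module (COG set + full organism set)
module_keys <- function(modules) {
  vapply(seq_len(nrow(modules)), function(i) {
    paste(
      paste(modules$cogs[[i]], collapse = ";"),
      paste(sort(c(modules$positive_orgs[[i]], modules$negative_orgs[[i]]),
                 method = "radix"), collapse = ";"),
      sep = "|"
    )
  }, character(1))
}

expect_same_modules <- function(a, b) {
  expect_setequal(module_keys(a), module_keys(b))
}

# independent upper-tail hypergeometric oracle: direct summation of the
# combinatorial formula (never goes through phyper)
hyper_tail_oracle <- function(population, successes, sample, observed) {
  if (observed == 0) return(1)
  i <- observed:sample # choose() vanishes outside the feasible range
  sum(choose(successes, i) * choose(population - successes, sample - i)) /
    choose(population, sample)
}

# vertex ids of a module in a network, from the exact per-organism sets
module_vids <- function(net, modules, i) {
  oc <- modules$org_cogs[[i]]
  v <- net$vertices
  unlist(lapply(names(oc), function(o) {
    v$vid[v$organism == o & v$cog %in% oc[[o]]]
  }))
}
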