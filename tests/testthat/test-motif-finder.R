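test_that("toy cohort enumeration matches the brute-force-derived modules", {
  net <- toy_network()
  m <- enumerate_ab_cliques(net, 2, 0)
  expect_equal(nrow(m), 1)
  expect_equal(m$cogs[[1]], c("c1", "c2"))
  expect_equal(m$positive_orgs[[1]], c("A", "B"))
  expect_equal(m$negative_orgs[[1]], character(0))

  m21 <- enumerate_ab_cliques(net, 2, 1)
  expect_equal(nrow(m21), 2)
  expect_setequal(
    module_keys(m21),
    c("c1;c2|A;B", "c1|A;B;C")
  )

  # only two positive organisms exist
  for (b in 0:1) expect_equal(nrow(enumerate_ab_cliques(net, 3, b)), 0)
  expect_error(enumerate_ab_cliques(net, -1, 0),
               class = "abmotif_parameter_error")
  expect_error(enumerate_ab_cliques(net, 1, 0.5),
               class = "abmotif_parameter_error")
})

test_that("bounded search equals the exhaustive oracle on random cohorts", {
  modes <- c("none", "beta_only", "alpha_beta")
  for (seed in 1:25) {
    net <- random_small_network(seed)
    counts <- table(factor(net$organisms$phenotype, c("positive", "negative")))
    for (alpha in 0:counts[["positive"]]) {
      for (beta in 0:counts[["negative"]]) {
        ref <- oracle_ab_cliques(net, alpha, beta)
        for (mode in modes) {
          got <- enumerate_ab_cliques(net, alpha, beta, bound_mode = mode)
          expect_identical(module_keys(got), module_keys(ref))
        }
      }
    }
  }
})

test_that("enumerated modules are maximal cliques with coherent reporting", {
  for (seed in 26:31) {
    net <- random_small_network(seed)
    n_neg <- sum(net$organisms$phenotype == "negative")
    m <- enumerate_ab_cliques(net, 0, n_neg)
    # exact clique identity (per-organism vertex sets) is duplicate-free
    expect_false(anyDuplicated(abmotif:::vertex_set_key(m)) > 0)
    n <- nrow(net$vertices)
    for (i in seq_len(nrow(m))) {
      vids <- module_vids(net, m, i)
      # reported COG set is the union over participating organisms,
      # organism sets are exactly the participants
      expect_equal(m$cogs[[i]],
                   sort(unique(unlist(m$org_cogs[[i]])), method = "radix"))
      expect_setequal(names(m$org_cogs[[i]]),
                      c(m$positive_orgs[[i]], m$negative_orgs[[i]]))
      # the product flag matches the vertex count
      n_orgs <- length(m$org_cogs[[i]])
      expect_equal(m$is_product[i], length(vids) == n_orgs * m$n_cogs[i])
      # clique: all pairs adjacent
      for (a in vids) {
        expect_true(all(setdiff(vids, a) %in% net$adj[[a]]))
      }
      # maximal: no outside vertex is adjacent to every module vertex
      outside <- setdiff(seq_len(n), vids)
      extendable <- vapply(outside, function(u) {
        all(vids %in% net$adj[[u]])
      }, logical(1))
      expect_false(any(extendable))
    }
  }
})

test_that("module sets are anti-monotone in alpha and monotone in beta", {
  for (seed in 32:36) {
    net <- random_small_network(seed)
    counts <- table(factor(net$organisms$phenotype, c("positive", "negative")))
    n_pos <- counts[["positive"]]; n_neg <- counts[["negative"]]
    for (beta in 0:n_neg) {
      prev <- NULL
      for (alpha in n_pos:0) {
        cur <- module_keys(enumerate_ab_cliques(net, alpha, beta))
        if (!is.null(prev)) expect_true(all(prev %in% cur))
        prev <- cur
      }
    }
    for (alpha in 0:n_pos) {
      prev <- NULL
      for (beta in 0:n_neg) {
        cur <- module_keys(enumerate_ab_cliques(net, alpha, beta))
        if (!is.null(prev)) expect_true(all(prev %in% cur))
        prev <- cur
      }
    }
  }
})

test_that("complete multipartite worst-case family yields 3^k maximal cliques", {
  for (k in 2:3) {
    net <- multipartite_network(k, 3)
    m <- enumerate_ab_cliques(net, 0, 0)
    expect_equal(nrow(m), 3^k)
    expect_equal(nrow(oracle_ab_cliques(net, 0, 0)), 3^k)
  }
})

test_that("the oracle enforces its exhaustive-size guard and handles empty input", {
  net <- multipartite_network(3, 3)
  expect_error(oracle_ab_cliques(net, 0, 0, max_vertices = 5),
               class = "abmotif_size_error")
  empty <- build_divided_network(
    tibble::tibble(organism = character(), node1 = character(),
                   node2 = character(), combined_score = integer()),
    tibble::tibble(organism = "Z", phenotype = "positive"),
    800
  )
  expect_equal(nrow(oracle_ab_cliques(empty, 0, 0)), 0)
  expect_equal(nrow(enumerate_ab_cliques(empty, 0, 0)), 0)
})

test_that("parameter grid counts match enumeration and are monotone", {
  net <- toy_network()
  g <- scan_parameter_grid(net, alphas = 0:3, betas = 0:1)
  cell <- function(a, b) g$n_cliques[g$alpha == a & g$beta == b]
  expect_equal(cell(2, 1), 2)
  expect_equal(cell(2, 0), 1)
  expect_equal(cell(3, 0), 0)
  expect_equal(cell(0, 1), nrow(oracle_ab_cliques(net, 0, 1)))

  for (seed in 37:39) {
    netr <- random_small_network(seed)
    n_neg <- sum(netr$organisms$phenotype == "negative")
    gr <- scan_parameter_grid(netr)
    # non-increasing along alpha, non-decreasing along beta
    for (b in unique(gr$beta)) {
      col <- gr$n_cliques[gr$beta == b][order(gr$alpha[gr$beta == b])]
      expect_true(all(diff(col) <= 0))
    }
    for (a in unique(gr$alpha)) {
      row <- gr$n_cliques[gr$alpha == a][order(gr$beta[gr$alpha == a])]
      expect_true(all(diff(row) >= 0))
    }
    expect_equal(
      max(gr$n_cliques),
      gr$n_cliques[gr$alpha == 0 & gr$beta == n_neg]
    )
    # grid agrees with direct per-cell enumeration on spot checks
    expect_equal(
      gr$n_cliques[gr$alpha == max(gr$alpha) & gr$beta == 0],
      nrow(enumerate_ab_cliques(netr, max(gr$alpha), 0))
    )
  }
})

test_that("search bounds prune the tree but never change the output", {
  for (seed in 40:44) {
    net <- random_small_network(seed)
    counts <- table(factor(net$organisms$phenotype, c("positive", "negative")))
    n_neg <- counts[["negative"]]
    alpha <- max(1, counts[["positive"]] - 1)
    bb <- benchmark_bounds(net, alpha, 0)
    nodes <- setNames(bb$nodes, bb$bound_mode)
    expect_lte(nodes[["alpha_beta"]], nodes[["beta_only"]])
    expect_lte(nodes[["beta_only"]], nodes[["none"]])
    # at the all-cliques setting the bounds never trigger
    bb0 <- benchmark_bounds(net, 0, n_neg)
    expect_equal(length(unique(bb0$nodes)), 1)
  }
})
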