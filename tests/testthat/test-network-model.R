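test_that("divided network construction matches the hand-derived toy cases", {
  # both organisms carry c1-c2 above threshold: the four vertices of the
  # two divisions form a complete graph (2 intra, 2 orthology, 2 conserved)
  toy <- toy_cohort()
  net <- build_divided_network(
    toy$links[toy$links$organism %in% c("A", "B"), ],
    toy$annotations[toy$annotations$organism %in% c("A", "B"), ],
    edge_threshold = 800
  )
  expect_equal(nrow(net$vertices), 4)
  expect_equal(nrow(net$intra_edges), 2)
  expect_equal(sum(net$inter_edges$kind == "orthology"), 2)
  expect_equal(sum(net$inter_edges$kind == "conserved_association"), 2)
  expect_true(all(lengths(net$adj) == 3)) # complete graph on 4 vertices

  # B's association falls below the threshold: conservation needs both sides
  net2 <- build_divided_network(
    tibble::tibble(
      organism = c("A", "B"), node1 = "c1", node2 = "c2",
      combined_score = c(900L, 700L)
    ),
    toy$annotations[toy$annotations$organism %in% c("A", "B"), ],
    edge_threshold = 800
  )
  expect_equal(nrow(net2$vertices), 4)
  expect_equal(nrow(net2$intra_edges), 1)
  expect_equal(sum(net2$inter_edges$kind == "orthology"), 2)
  expect_equal(sum(net2$inter_edges$kind == "conserved_association"), 0)

  # single organism: no cross-division pairs exist
  net3 <- build_divided_network(
    toy$links[toy$links$organism == "A", ],
    toy$annotations[toy$annotations$organism == "A", ],
    edge_threshold = 800
  )
  expect_equal(nrow(net3$inter_edges), 0)
})

test_that("construction rejects inconsistent configuration", {
  toy <- toy_cohort()
  expect_error(
    build_divided_network(toy$links, toy$annotations[1, ], 800),
    class = "abmotif_config_error"
  )
  expect_error(
    build_divided_network(
      toy$links, rbind(toy$annotations, toy$annotations[1, ]), 800
    ),
    class = "abmotif_config_error"
  )
  bad <- toy$links
  bad$combined_score[1] <- 1200L
  expect_error(build_divided_network(bad, toy$annotations, 800),
               class = "abmotif_parse_error")
  expect_error(build_divided_network(toy$links, toy$annotations, 1500),
               class = "abmotif_parameter_error")
  ann_bad <- toy$annotations
  ann_bad$phenotype[1] <- "maybe"
  expect_error(build_divided_network(toy$links, ann_bad, 800),
               class = "abmotif_config_error")
})

test_that("reversed duplicate input edges merge keeping the maximum score", {
  links <- tibble::tibble(
    organism = "A",
    node1 = c("c1", "c2", "c1"),
    node2 = c("c2", "c1", "c1"), # includes a self-loop, dropped
    combined_score = c(650L, 820L, 999L)
  )
  ann <- tibble::tibble(organism = "A", phenotype = "positive")
  net <- build_divided_network(links, ann, 0)
  expect_equal(nrow(net$intra_edges), 1)
  expect_equal(net$intra_edges$score, 820L)
})

test_that("divisions partition the vertex set and conserved edges obey the iff rule", {
  for (seed in 1:6) {
    net <- random_small_network(seed)
    v <- net$vertices
    # partition: division sizes sum to the vertex count, no duplicates
    expect_equal(sum(table(v$organism)), nrow(v))
    expect_false(anyDuplicated(paste(v$organism, v$cog)) > 0)
    # every intra edge within one division, every inter edge across two
    expect_true(all(net$inter_edges$organism1 != net$inter_edges$organism2))
    orth <- net$inter_edges[net$inter_edges$kind == "orthology", ]
    expect_true(all(orth$cog1 == orth$cog2))

    # exhaustive iff check of the conservation criteria
    intra_key <- with(net$intra_edges, paste(organism, cog1, cog2))
    cons_key <- with(
      net$inter_edges[net$inter_edges$kind == "conserved_association", ],
      paste(organism1, cog1, organism2, cog2)
    )
    orgs <- net$organisms$organism
    cogs <- sort(unique(v$cog), method = "radix")
    for (a in orgs) for (b in orgs) {
      if (a >= b) next
      for (i in seq_along(cogs)) for (j in seq_along(cogs)) {
        if (i == j) next
        c1 <- min(cogs[i], cogs[j]); c2 <- max(cogs[i], cogs[j])
        both <- paste(a, c1, c2) %in% intra_key &&
          paste(b, c1, c2) %in% intra_key
        expect_equal(paste(a, cogs[i], b, cogs[j]) %in% cons_key, both)
      }
    }
  }
})

test_that("inter-edge count respects the combinatorial cap", {
  for (seed in 7:10) {
    par <- random_small_params(seed)
    coh <- generate_cohort(par)
    net <- build_divided_network(coh$links, coh$annotations, 700,
                                 nodes = coh$nodes)
    k <- nrow(net$organisms)
    n_max <- max(table(net$vertices$organism))
    cap <- choose(k, 2) * (n_max + 2 * choose(n_max, 2))
    expect_lte(nrow(net$inter_edges), cap)
  }
})

test_that("raising the edge threshold only shrinks the network", {
  coh <- generate_cohort(random_small_params(11))
  thresholds <- c(0, 400, 700, 900, 999)
  nets <- lapply(thresholds, function(t) {
    build_divided_network(coh$links, coh$annotations, t, nodes = coh$nodes)
  })
  for (i in seq_along(nets)[-1]) {
    expect_equal(nrow(nets[[i]]$vertices), nrow(nets[[1]]$vertices))
    expect_lte(nrow(nets[[i]]$intra_edges), nrow(nets[[i - 1]]$intra_edges))
    lo <- nets[[i - 1]]; hi <- nets[[i]]
    expect_true(all(
      with(hi$intra_edges, paste(organism, cog1, cog2)) %in%
        with(lo$intra_edges, paste(organism, cog1, cog2))
    ))
    expect_true(all(
      with(hi$inter_edges, paste(organism1, cog1, organism2, cog2)) %in%
        with(lo$inter_edges, paste(organism1, cog1, organism2, cog2))
    ))
  }
})

test_that("type_count counts organisms, not vertices", {
  net <- toy_network()
  v <- net$vertices
  expect_equal(type_count(net, integer(0), "positive"), 0)
  expect_equal(type_count(net, integer(0), "negative"), 0)
  all_v <- v$vid
  expect_equal(type_count(net, all_v, "positive"), 2)
  expect_equal(type_count(net, all_v, "negative"), 1)
  # several vertices of one organism count that organism once
  a_only <- v$vid[v$organism == "A"]
  expect_equal(type_count(net, a_only, "positive"), 1)
  # accepts (organism, cog) frames; rejects unknown vertices
  expect_equal(
    type_count(net, tibble::tibble(organism = "C", cog = "c1"), "negative"), 1
  )
  expect_error(type_count(net, max(v$vid) + 1L, "positive"),
               class = "abmotif_input_error")
  expect_error(
    type_count(net, tibble::tibble(organism = "C", cog = "c9"), "negative"),
    class = "abmotif_input_error"
  )
})

test_that("protein-to-COG projection aggregates, drops and reports correctly", {
  edges <- tibble::tibble(
    protein1 = c("pA", "pC", "pE", "pF"),
    protein2 = c("pB", "pD", "pE2", "pG"),
    combined_score = c(650L, 820L, 700L, 500L)
  )
  mapping <- tibble::tibble(
    protein = c("pA", "pB", "pC", "pD", "pE", "pE2"),
    cog = c("c1", "c2", "c1", "c2", "c3", "c3")
  )
  proj <- project_proteins_to_cogs(edges, mapping, organism = "X")
  # two protein pairs collapse onto (c1, c2): maximum score wins
  expect_equal(nrow(proj$links), 1)
  expect_equal(proj$links$combined_score, 820L)
  # (pE, pE2) maps onto (c3, c3): dropped, but c3 is still present
  expect_true("c3" %in% proj$cogs$cog)
  expect_setequal(proj$unmapped, c("pF", "pG"))

  # fully unmapped input: empty network, everything reported
  proj2 <- project_proteins_to_cogs(edges[4, ], mapping[0, ], organism = "X")
  expect_equal(nrow(proj2$links), 0)
  expect_equal(nrow(proj2$cogs), 0)
  expect_setequal(proj2$unmapped, c("pF", "pG"))

  bad <- edges
  bad$combined_score[1] <- NA
  expect_error(project_proteins_to_cogs(bad, mapping, "X"),
               class = "abmotif_parse_error")
})
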