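test_that("cohort generation is deterministic and insulated per organism", {
  par <- random_small_params(3)
  expect_identical(generate_cohort(par), generate_cohort(par))

  # adding organisms must not perturb existing organisms' networks
  par_small <- cohort_params(
    n_pos = 3, n_neg = 2, universe_size = 10, presence_prob = 0.7,
    background_edge_prob = 0.3, seed = 11
  )
  par_big <- cohort_params(
    n_pos = 3, n_neg = 3, universe_size = 10, presence_prob = 0.7,
    background_edge_prob = 0.3, seed = 11
  )
  small <- generate_cohort(par_small)
  big <- generate_cohort(par_big)
  keep <- small$annotations$organism
  expect_identical(
    small$links,
    big$links[big$links$organism %in% keep, ]
  )
})

test_that("planted modules appear as exact cliques in exactly their carriers", {
  pm <- planted_module(c("COG0001", "COG0002", "COG0003"),
                       positive_carriers = sprintf("pos_%02d", 1:4),
                       edge_score = 880L)
  par <- cohort_params(
    n_pos = 5, n_neg = 3, universe_size = 8, presence_prob = 0.5,
    background_edge_prob = 0, planted = list(pm), seed = 21
  )
  coh <- generate_cohort(par)
  # with no background edges, every carrier network is exactly the 3-clique
  for (org in pm$positive_carriers) {
    e <- coh$links[coh$links$organism == org, ]
    expect_equal(nrow(e), 3)
    expect_true(all(e$combined_score == 880L))
  }
  non_carriers <- setdiff(coh$annotations$organism, pm$positive_carriers)
  expect_false(any(coh$links$organism %in% non_carriers))
  expect_equal(nrow(coh$ground_truth), 1)
  expect_equal(coh$ground_truth$cogs[[1]], sort(pm$cog_ids, method = "radix"))
})

test_that("planted carriers and COGs are validated against the cohort", {
  pm_bad_org <- planted_module(c("COG0001", "COG0002"),
                               positive_carriers = "pos_99")
  expect_error(
    generate_cohort(cohort_params(n_pos = 3, n_neg = 1,
                                  planted = list(pm_bad_org), seed = 1)),
    class = "abmotif_parameter_error"
  )
  pm_wrong_type <- planted_module(c("COG0001", "COG0002"),
                                  positive_carriers = "neg_01")
  expect_error(
    generate_cohort(cohort_params(n_pos = 3, n_neg = 1,
                                  planted = list(pm_wrong_type), seed = 1)),
    class = "abmotif_parameter_error"
  )
  pm_bad_cog <- planted_module(c("COG9999", "COG0002"),
                               positive_carriers = "pos_01")
  expect_error(
    generate_cohort(cohort_params(n_pos = 3, n_neg = 1, universe_size = 5,
                                  planted = list(pm_bad_cog), seed = 1)),
    class = "abmotif_parameter_error"
  )
  expect_error(planted_module("COG0001", "pos_01"),
               class = "abmotif_parameter_error")
})

test_that("noise-free planted modules are recovered exactly by the finder", {
  pm <- planted_module(c("COG0002", "COG0005", "COG0007"),
                       positive_carriers = sprintf("pos_%02d", 1:4),
                       edge_score = 900L)
  for (seed in 1:10) {
    par <- cohort_params(
      n_pos = 5, n_neg = 3, universe_size = 8, presence_prob = 1,
      background_edge_prob = 0, planted = list(pm), seed = seed
    )
    coh <- generate_cohort(par)
    net <- build_divided_network(coh$links, coh$annotations, 800,
                                 nodes = coh$nodes)
    # at (carriers+, 0) with min_cogs 2 the planted module is the only output
    m <- enumerate_ab_cliques(net, 4, 0, min_cogs = 2)
    expect_equal(nrow(m), 1)
    expect_equal(m$cogs[[1]], pm$cog_ids[order(pm$cog_ids)])
    expect_equal(m$positive_orgs[[1]], sort(pm$positive_carriers))
    # recoverable at any laxer setting too
    for (alpha in 0:4) {
      got <- enumerate_ab_cliques(net, alpha, 1, min_cogs = 2)
      expect_true(any(vapply(got$cogs, function(cs) {
        all(pm$cog_ids %in% cs)
      }, logical(1))))
    }
  }
})

test_that("generated distance matrices are valid and deterministic", {
  ids <- sprintf("o%d", 1:6)
  dm <- generate_distance_matrix(ids, seed = 4, scale = 2)
  expect_identical(dm, generate_distance_matrix(ids, seed = 4, scale = 2))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  off <- dm[upper.tri(dm)]
  expect_true(all(off > 0 & off <= 2))

  # positives-only planted module scores 1 on any generated matrix
  expect_equal(phylo_score(ids[1:3], character(0), dm), 1)
})

test_that("written cohorts read back through the pipeline input parsers", {
  pm <- planted_module(c("COG0001", "COG0003"),
                       positive_carriers = c("pos_01", "pos_02"))
  par <- cohort_params(n_pos = 3, n_neg = 2, universe_size = 6,
                       presence_prob = 0.8, background_edge_prob = 0.2,
                       planted = list(pm), seed = 8)
  coh <- generate_cohort(par)
  dm <- generate_distance_matrix(coh$annotations$organism, seed = 8)
  dir <- tempfile()
  paths <- write_cohort(coh, dir, dm = dm)
  links <- read_links(paths[["links"]])
  expect_equal(as.data.frame(links), as.data.frame(coh$links))
  ann <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(
    as.data.frame(ann),
    as.data.frame(dplyr::arrange(coh$annotations, organism))
  )
  expect_equal(read_distance_matrix(paths[["distances"]]), dm)
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$edge_score, coh$ground_truth$edge_score)
})
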