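#' Describe a module planted into a synthetic cohort
#'
#' A planted module is a COG set inserted as a complete clique (all
#' `C(m, 2)` edges at `edge_score`) into exactly the listed carrier
#' organisms; it is the recoverable ground truth for end-to-end tests of
#' the enumeration pipeline.
#'
#' @param cog_ids Character vector of at least two COG ids.
#' @param positive_carriers,negative_carriers Organism ids receiving the
#'   full clique.
#' @param edge_score Integer score (0--999) given to every module edge
#'   (default 900, comfortably above a STRING-style high-confidence
#'   threshold).
#' @return A `planted_module` list.
#' @export
planted_module <- function(cog_ids, positive_carriers,
                           negative_carriers = character(),
                           edge_score = 900L) {
  cog_ids <- as.character(cog_ids)
  if (length(cog_ids) < 2 || anyDuplicated(cog_ids)) {
    abort_param("`cog_ids` must hold at least two distinct COG ids")
  }
  if (!is.numeric(edge_score) || edge_score < 0 || edge_score > 999) {
    abort_param("`edge_score` must be an integer in [0, 999]")
  }
  structure(
    list(
      cog_ids = cog_ids,
      positive_carriers = as.character(positive_carriers),
      negative_carriers = as.character(negative_carriers),
      edge_score = as.integer(edge_score)
    ),
    class = "planted_module"
  )
}

#' Parameters for a synthetic organism cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: a cohort
#' of phenotype-positive and -negative organisms over a shared COG
#' universe, sparse random background associations, and optional planted
#' conserved modules. The defaults mirror a hydrogen-production-sized
#' comparative study: 9 positive and 8 negative organisms, with each
#' background COG present in an organism with probability 0.6 and each
#' present COG pair associated with probability 0.08 at a uniform score in
#' 400--999 (so roughly half of background edges survive a high-confidence
#' threshold of 700-800).
#'
#' @param n_pos,n_neg Numbers of positive / negative organisms.
#' @param universe_size Number of COGs in the shared universe.
#' @param presence_prob Probability a background COG appears in an
#'   organism.
#' @param background_edge_prob Probability of a background association per
#'   present COG pair.
#' @param background_score_range Integer interval for background edge
#'   scores.
#' @param planted List of [planted_module()] objects.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_pos = 9L, n_neg = 8L, universe_size = 25L,
                          presence_prob = 0.6, background_edge_prob = 0.08,
                          background_score_range = c(400L, 999L),
                          planted = list(), seed = 1L) {
  if (n_pos < 1 || n_neg < 0) abort_param("need n_pos >= 1 and n_neg >= 0")
  if (universe_size < 1) abort_param("`universe_size` must be >= 1")
  probs <- c(presence_prob, background_edge_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_param("probabilities must lie in [0, 1]")
  }
  r <- as.integer(background_score_range)
  if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 999) {
    abort_param("`background_score_range` must be an ascending pair in [0, 999]")
  }
  if (!all(vapply(planted, inherits, logical(1), "planted_module"))) {
    abort_param("`planted` must be a list of planted_module objects")
  }
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      universe_size = as.integer(universe_size),
      presence_prob = presence_prob,
      background_edge_prob = background_edge_prob,
      background_score_range = r,
      planted = planted, seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

cohort_organism_ids <- function(params) {
  c(
    sprintf("pos_%02d", seq_len(params$n_pos)),
    sprintf("neg_%02d", seq_len(params$n_neg))
  )
}

cohort_cog_ids <- function(params) {
  sprintf("COG%04d", seq_len(params$universe_size))
}

#' Generate a seeded synthetic cohort with planted conserved modules
#'
#' Draws one functional association network per organism: each COG of the
#' universe is present with `presence_prob`, each unordered pair of present
#' COGs is associated with `background_edge_prob` at a uniform integer
#' score from `background_score_range`, and every planted module's COGs are
#' then forced present and fully connected at the module's `edge_score` in
#' exactly its carrier organisms (overlapping background edges keep the
#' larger score, matching the max-merge rule for duplicate edges).
#'
#' Each organism draws from its own RNG stream (seeded from `seed` and the
#' organism's index), so adding organisms to a cohort never perturbs the
#' networks of existing ones.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `synthetic_cohort`: `links` (tibble `organism`,
#'   `node1`, `node2`, `combined_score`), `nodes` (COG presence tibble),
#'   `annotations` (phenotype table), and `ground_truth` (tibble of planted
#'   modules with carrier lists).
#' @examples
#' coh <- generate_cohort(cohort_params(n_pos = 3, n_neg = 2, seed = 7))
#' dplyr::count(coh$links, organism)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  orgs <- cohort_organism_ids(params)
  cogs <- cohort_cog_ids(params)
  annotations <- tibble(
    organism = orgs,
    phenotype = rep(c("positive", "negative"), c(params$n_pos, params$n_neg))
  )
  for (pm in params$planted) {
    carriers <- c(pm$positive_carriers, pm$negative_carriers)
    if (!all(carriers %in% orgs)) {
      abort_param(sprintf(
        "planted carrier(s) not in the cohort: %s",
        paste(setdiff(carriers, orgs), collapse = ", ")
      ))
    }
    pos_ok <- pm$positive_carriers %in% orgs[annotations$phenotype == "positive"]
    neg_ok <- pm$negative_carriers %in% orgs[annotations$phenotype == "negative"]
    if (!all(pos_ok) || !all(neg_ok)) {
      abort_param("planted carriers must match their organisms' phenotypes")
    }
    if (!all(pm$cog_ids %in% cogs)) {
      abort_param("planted COG ids must belong to the cohort universe")
    }
  }

  per_org <- lapply(seq_along(orgs), function(i) {
    org <- orgs[i]
    # independent per-organism stream: organisms are insulated from each other
    set.seed((params$seed + 7919L * i) %% .Machine$integer.max)
    present <- cogs[runif(length(cogs)) < params$presence_prob]
    edges <- NULL
    if (length(present) >= 2 && params$background_edge_prob > 0) {
      pairs <- utils::combn(present, 2)
      hit <- runif(ncol(pairs)) < params$background_edge_prob
      if (any(hit)) {
        lo <- params$background_score_range[1]
        hi <- params$background_score_range[2]
        edges <- tibble(
          organism = org,
          node1 = pairs[1, hit],
          node2 = pairs[2, hit],
          combined_score = as.integer(
            lo + floor(runif(sum(hit)) * (hi - lo + 1))
          )
        )
      }
    }
    list(present = tibble(organism = org, cog = present), edges = edges)
  })

  nodes <- dplyr::bind_rows(lapply(per_org, `[[`, "present"))
  links <- dplyr::bind_rows(lapply(per_org, `[[`, "edges"))
  if (nrow(links) == 0) {
    links <- tibble(
      organism = character(), node1 = character(), node2 = character(),
      combined_score = integer()
    )
  }

  # plant modules: force presence + full clique at edge_score in carriers
  for (pm in params$planted) {
    carriers <- c(pm$positive_carriers, pm$negative_carriers)
    pairs <- utils::combn(sort_c(pm$cog_ids), 2)
    for (org in carriers) {
      nodes <- dplyr::bind_rows(nodes, tibble(organism = org, cog = pm$cog_ids))
      links <- dplyr::bind_rows(links, tibble(
        organism = org, node1 = pairs[1, ], node2 = pairs[2, ],
        combined_score = pm$edge_score
      ))
    }
  }
  nodes <- distinct(nodes)
  nodes <- nodes[order_c(nodes$organism, nodes$cog), , drop = FALSE]
  links <- normalise_links(links)

  ground_truth <- tibble(
    module = seq_along(params$planted),
    cogs = lapply(params$planted, function(pm) sort_c(pm$cog_ids)),
    positive_carriers = lapply(params$planted, function(pm) {
      sort_c(pm$positive_carriers)
    }),
    negative_carriers = lapply(params$planted, function(pm) {
      sort_c(pm$negative_carriers)
    }),
    edge_score = vapply(params$planted, `[[`, integer(1), "edge_score")
  )

  structure(
    list(
      links = links, nodes = nodes, annotations = annotations,
      ground_truth = ground_truth, params = params
    ),
    class = "synthetic_cohort"
  )
}

#' Generate a random symmetric organism distance matrix
#'
#' Entries are drawn uniformly from `(0, scale]`, symmetrised, with a zero
#' diagonal; fully determined by `seed`. A stand-in for a real phylogenetic
#' distance table when exercising the diversity score on synthetic cohorts.
#'
#' @param organism_ids Character vector of organism ids.
#' @param seed Integer seed.
#' @param scale Upper bound of the distances (default 1).
#' @return A symmetric matrix validated by [as_phylo_dist()].
#' @export
generate_distance_matrix <- function(organism_ids, seed = 1L, scale = 1) {
  organism_ids <- as.character(organism_ids)
  n <- length(organism_ids)
  if (n < 1) abort_param("`organism_ids` must be non-empty")
  if (scale <= 0) abort_param("`scale` must be positive")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  m <- matrix(0, n, n, dimnames = list(organism_ids, organism_ids))
  if (n > 1) {
    upper <- which(upper.tri(m))
    m[upper] <- scale * (1 - runif(length(upper))) # in (0, scale]
    m <- m + t(m)
  }
  as_phylo_dist(m)
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Emits `links.tsv` (organism, node1, node2, combined_score),
#' `nodes.tsv`, `phenotypes.tsv`, `distances.tsv` (labelled square TSV)
#' and `ground_truth.json` under `dir`, so a generated cohort can be fed
#' back through the file-based pipeline entry points unchanged.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param dm Optional distance matrix to include.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, dm = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    links = file.path(dir, "links.tsv"),
    nodes = file.path(dir, "nodes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(cohort$links, paths[["links"]])
  readr::write_tsv(cohort$nodes, paths[["nodes"]])
  readr::write_tsv(cohort$annotations, paths[["phenotypes"]])
  gt <- lapply(seq_len(nrow(cohort$ground_truth)), function(i) {
    list(
      cogs = cohort$ground_truth$cogs[[i]],
      positive_carriers = cohort$ground_truth$positive_carriers[[i]],
      negative_carriers = cohort$ground_truth$negative_carriers[[i]],
      edge_score = cohort$ground_truth$edge_score[[i]]
    )
  })
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE)
  if (!is.null(dm)) {
    dm <- as_phylo_dist(dm)
    path_dm <- file.path(dir, "distances.tsv")
    df <- data.frame(organism = rownames(dm), dm, check.names = FALSE)
    readr::write_tsv(df, path_dm)
    paths <- c(paths, distances = path_dm)
  }
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d organisms, %d COG universe, %d edges, %d planted module(s), seed %d\n",
    nrow(x$annotations), x$params$universe_size, nrow(x$links),
    nrow(x$ground_truth), x$params$seed
  ))
  invisible(x)
}
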