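#' Read a STRING-dialect links file
#'
#' Whitespace- or tab-separated edge list. Two dialects are accepted: three
#' columns (`node1 node2 combined_score`, one file per organism -- supply
#' `organism`) or four columns with a leading organism column. A header
#' line is detected by a non-numeric score field and skipped.
#'
#' @param path File path.
#' @param organism Organism id for the three-column dialect.
#' @return A tibble `organism`, `node1`, `node2`, `combined_score`.
#' @export
read_links <- function(path, organism = NULL) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'", path))
  first <- readLines(path, n = 1L)
  tok <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (!length(tok) %in% c(3L, 4L)) {
    abort_parse(sprintf(
      "'%s': expected 3 or 4 whitespace-separated columns, found %d",
      path, length(tok)
    ))
  }
  has_header <- is.na(suppressWarnings(as.numeric(tok[length(tok)])))
  df <- read.table(path, header = FALSE, skip = as.integer(has_header),
                   stringsAsFactors = FALSE,
                   col.names = if (length(tok) == 4) {
                     c("organism", "node1", "node2", "combined_score")
                   } else {
                     c("node1", "node2", "combined_score")
                   })
  if (length(tok) == 3) {
    if (is.null(organism)) {
      abort_config(sprintf(
        "'%s' has no organism column; supply `organism`", path
      ))
    }
    df$organism <- as.character(organism)
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1] + as.integer(has_header)
    abort_parse(sprintf("'%s' line %d: malformed combined_score", path, bad))
  }
  as_tibble(df[, c("organism", "node1", "node2", "combined_score")])
}

#' Read an organism phenotype table
#'
#' TSV with columns `organism`, `phenotype` (`positive` / `negative`);
#' a header line is detected and skipped.
#'
#' @param path File path.
#' @return A validated annotations tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'", path))
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  has_header <- length(first) >= 2 &&
    !first[2] %in% c("positive", "negative")
  df <- read.table(path, header = FALSE, skip = as.integer(has_header),
                   stringsAsFactors = FALSE,
                   col.names = c("organism", "phenotype"))
  validate_annotations(as_tibble(df))
}

#' Read a protein-to-COG mapping table
#'
#' TSV with columns `organism`, `protein`, `cog`.
#'
#' @param path File path.
#' @return A tibble with those three character columns.
#' @export
read_cog_mapping <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'", path))
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  if (length(first) != 3) {
    abort_parse(sprintf("'%s': expected 3 columns", path))
  }
  has_header <- identical(tolower(first),
                          c("organism", "protein", "cog"))
  df <- read.table(path, header = FALSE, skip = as.integer(has_header),
                   stringsAsFactors = FALSE,
                   col.names = c("organism", "protein", "cog"))
  as_tibble(df)
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `pairs` (an explicit data frame of `alpha`, `beta`
#' values) or `auto_params = TRUE` (hypergeometric selection at
#' `p_threshold`, see [select_ab_pairs()]) must be active.
#'
#' @param links,phenotypes Input tables (tibbles) or file paths.
#' @param nodes Optional COG presence table or path (declares isolated
#'   COGs).
#' @param distances Optional distance matrix, or path readable by
#'   [read_distance_matrix()]; enables phylogenetic scores.
#' @param edge_threshold Intra-edge confidence threshold (0--999).
#' @param pairs Optional data frame with columns `alpha`, `beta`.
#' @param auto_params Select pairs automatically (default if `pairs` is
#'   missing).
#' @param p_threshold Significance threshold for automatic pair selection.
#' @param bound_mode Search-bound mode for [enumerate_ab_cliques()].
#' @param min_cogs Minimum distinct COGs per reported module.
#' @param out_dir Optional output directory (TSV + JSON + manifest).
#' @param seed Integer seed recorded in the manifest (the core pipeline is
#'   deterministic; the seed matters for downstream subsampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(links, phenotypes, nodes = NULL,
                            distances = NULL, edge_threshold = 700L,
                            pairs = NULL, auto_params = is.null(pairs),
                            p_threshold = 0.005,
                            bound_mode = "alpha_beta", min_cogs = 1L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(pairs) == !isTRUE(auto_params)) {
    abort_config(
      "exactly one of explicit `pairs` or `auto_params = TRUE` must be active"
    )
  }
  if (!is.null(pairs)) check_columns(pairs, c("alpha", "beta"), "pairs")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort_config("`p_threshold` must be in (0, 1]")
  }
  if (edge_threshold < 0 || edge_threshold > 999) {
    abort_config("`edge_threshold` must be in [0, 999]")
  }
  structure(
    list(
      links = links, phenotypes = phenotypes, nodes = nodes,
      distances = distances, edge_threshold = as.integer(edge_threshold),
      pairs = pairs, auto_params = isTRUE(auto_params),
      p_threshold = p_threshold, bound_mode = bound_mode,
      min_cogs = as.integer(min_cogs), out_dir = out_dir,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

resolve_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full module-discovery pipeline
#'
#' Orchestrates the four method steps: (1) build the two-typed, divided
#' network at the configured edge threshold; (2) take the explicit
#' (alpha, beta) pairs or select significant non-redundant pairs by the
#' hypergeometric test; (3) enumerate the (alpha, beta)-cliques for every
#' pair and deduplicate modules across pairs (the union equals the output
#' at the loosest pair); (4) attach each module's phenotype-bias p-value
#' and, when a distance matrix is supplied, its phylogenetic diversity
#' score. Modules are returned in canonical sorted order; with `out_dir`
#' set, a TSV, a JSON mirror and a run manifest are written.
#'
#' @param config A [pipeline_config()].
#' @return An `ab_modules` tibble with attributes `manifest` (named list)
#'   and `pairs` (the pairs used).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  links <- resolve_table(config$links, read_links)
  phenotypes <- resolve_table(config$phenotypes, read_phenotypes)
  nodes <- if (!is.null(config$nodes)) {
    resolve_table(config$nodes, function(p) {
      df <- read.table(p, header = TRUE, stringsAsFactors = FALSE)
      names(df) <- c("organism", "cog")
      as_tibble(df)
    })
  }
  dm <- if (!is.null(config$distances)) {
    if (is.character(config$distances)) {
      read_distance_matrix(config$distances)
    } else {
      as_phylo_dist(config$distances)
    }
  }

  phenotypes <- validate_annotations(phenotypes)
  n_pos <- sum(phenotypes$phenotype == "positive")
  n_neg <- sum(phenotypes$phenotype == "negative")
  if (n_pos == 0) {
    abort_config("cohort has no positive organisms")
  }

  net <- build_divided_network(links, phenotypes, config$edge_threshold,
                               nodes = nodes)

  pairs <- if (config$auto_params) {
    select_ab_pairs(n_pos, n_neg, config$p_threshold)
  } else {
    as_tibble(config$pairs[, c("alpha", "beta")])
  }
  if (nrow(pairs) == 0) {
    warn("no (alpha, beta) pair qualifies; returning an empty module table",
         class = "abmotif_no_pairs")
  }

  found <- lapply(seq_len(nrow(pairs)), function(i) {
    enumerate_ab_cliques(net, pairs$alpha[i], pairs$beta[i],
                         bound_mode = config$bound_mode,
                         min_cogs = config$min_cogs)
  })
  modules <- if (length(found) > 0) dplyr::bind_rows(found) else {
    cliques_to_modules(net, list())
  }
  modules <- modules[!duplicated(module_key(modules)), , drop = FALSE]
  modules <- canonicalise_modules(modules)
  modules <- clique_significance(modules, n_pos, n_neg)
  if (!is.null(dm)) modules <- add_phylo_scores(modules, dm)
  if (nrow(modules) == 0) {
    warn("no module satisfies any selected (alpha, beta) pair",
         class = "abmotif_empty_result")
  }

  manifest <- list(
    edge_threshold = config$edge_threshold,
    auto_params = config$auto_params,
    p_threshold = if (config$auto_params) config$p_threshold else NULL,
    pairs = lapply(seq_len(nrow(pairs)), function(i) {
      list(alpha = pairs$alpha[i], beta = pairs$beta[i])
    }),
    bound_mode = config$bound_mode,
    min_cogs = config$min_cogs,
    seed = config$seed,
    n_organisms = nrow(phenotypes),
    n_positive = n_pos,
    n_negative = n_neg,
    n_vertices = nrow(net$vertices),
    n_intra_edges = nrow(net$intra_edges),
    n_inter_edges = nrow(net$inter_edges),
    n_modules = nrow(modules),
    abmotif_version = as.character(utils::packageVersion("abmotif")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  out <- new_ab_modules(modules, manifest = manifest, pairs = pairs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_modules(out, file.path(config$out_dir, "modules.tsv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Select a network edge threshold against a validation COG set
#'
#' Walks a descending ladder of confidence thresholds (default 999, 950,
#' ..., 500). At each value the divided network is built, modules are
#' enumerated at the selected (alpha, beta) pairs, and accuracy is the
#' fraction of validation COGs recovered in at least one output module
#' (validation-set recall). The first ladder value reaching
#' `accuracy_target` is chosen; if none does, the value maximising
#' accuracy is returned with a warning. The report also tracks the number
#' of unique COGs incident to a surviving intra edge per threshold and its
#' successive differences -- a secondary diagnostic reported for human
#' judgment, never auto-applied.
#'
#' @param links,phenotypes Input tables or paths (as in
#'   [pipeline_config()]).
#' @param validation_cogs Non-empty character vector of known
#'   phenotype-related COGs.
#' @param accuracy_target Required recall (default 0.75).
#' @param ladder Descending integer thresholds to try.
#' @param p_threshold,pairs,min_cogs,nodes Passed through to the
#'   per-threshold pipeline run.
#' @return A list of class `threshold_report`: `threshold` (the selected
#'   value), `reached_target` (logical) and `report` (one row per ladder
#'   value: `threshold`, `accuracy`, `n_modules`, `unique_cogs`,
#'   `delta_unique_cogs`).
#' @export
select_edge_threshold <- function(links, phenotypes, validation_cogs,
                                  accuracy_target = 0.75,
                                  ladder = c(999L, seq(950L, 500L, by = -50L)),
                                  p_threshold = 0.005, pairs = NULL,
                                  min_cogs = 1L, nodes = NULL) {
  validation_cogs <- unique(as.character(validation_cogs))
  if (length(validation_cogs) == 0) {
    abort_param("`validation_cogs` must be non-empty")
  }
  if (any(ladder < 0 | ladder > 999)) {
    abort_param("ladder values must lie in [0, 999]")
  }
  links <- resolve_table(links, read_links)
  phenotypes <- validate_annotations(resolve_table(phenotypes,
                                                   read_phenotypes))
  rows <- lapply(ladder, function(thr) {
    cfg <- pipeline_config(
      links = links, phenotypes = phenotypes, nodes = nodes,
      edge_threshold = thr, pairs = pairs,
      auto_params = is.null(pairs), p_threshold = p_threshold,
      min_cogs = min_cogs
    )
    mods <- suppressWarnings(run_pipeline(cfg))
    found <- unique(unlist(mods$cogs))
    intra <- links[links$combined_score >= thr, , drop = FALSE]
    tibble(
      threshold = as.integer(thr),
      accuracy = mean(validation_cogs %in% found),
      n_modules = nrow(mods),
      unique_cogs = n_distinct(c(intra$node1, intra$node2))
    )
  })
  report <- dplyr::bind_rows(rows)
  report$delta_unique_cogs <- c(NA_integer_, diff(report$unique_cogs))
  hit <- which(report$accuracy >= accuracy_target)
  if (length(hit) > 0) {
    chosen <- report$threshold[hit[1]]
    reached <- TRUE
  } else {
    chosen <- report$threshold[which.max(report$accuracy)]
    reached <- FALSE
    warn(sprintf(
      "no ladder value reaches accuracy %.2f; returning the maximiser %d",
      accuracy_target, chosen
    ), class = "abmotif_threshold_fallback")
  }
  structure(
    list(threshold = chosen, reached_target = reached, report = report),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> selected threshold %d (target %s)\n",
    x$threshold, if (x$reached_target) "reached" else "NOT reached"
  ))
  print(x$report)
  invisible(x)
}

#' Stability of top-ranked modules under organism subsampling
#'
#' Checks whether the top-ranked modules depend on phylogenetically
#' redundant organisms: per trial, one organism is sampled from each group
#' (e.g. genus), a random subset of the sampled representatives (of size
#' drawn from `subset_size_range`) is kept, the pipeline is rerun on that
#' sub-cohort, and modules are ranked by (p-value ascending, phylogenetic
#' score descending). The report gives the pairwise overlap of the top-`n`
#' module lists across trials.
#'
#' @param links,phenotypes,nodes,distances Inputs as in
#'   [pipeline_config()]; `distances` is required (ranking uses the
#'   phylogenetic score as tie-breaker).
#' @param grouping Data frame `organism`, `group` covering at least every
#'   positive organism; ungrouped organisms are dropped from trials.
#' @param n_trials Number of subsampling trials.
#' @param subset_size_range Integer pair: per-trial sub-cohort size range.
#' @param seed Integer seed for the trial draws.
#' @param edge_threshold,p_threshold,pairs,min_cogs Pipeline settings.
#' @param top_n Length of the ranked list compared across trials.
#' @return A list of class `robustness_report`: `trials` (per-trial
#'   sub-cohort and top module keys), `overlaps` (pairwise trial overlap
#'   in `[0, 1]`), `mean_overlap`.
#' @export
subsample_robustness <- function(links, phenotypes, grouping,
                                 distances = NULL, nodes = NULL,
                                 n_trials = 5L, subset_size_range = c(8L, 13L),
                                 seed = 1L, edge_threshold = 700L,
                                 p_threshold = 0.005, pairs = NULL,
                                 min_cogs = 1L, top_n = 10L) {
  links <- resolve_table(links, read_links)
  phenotypes <- validate_annotations(resolve_table(phenotypes,
                                                   read_phenotypes))
  check_columns(grouping, c("organism", "group"), "grouping")
  grouping <- tibble(
    organism = as.character(grouping$organism),
    group = as.character(grouping$group)
  )
  positives <- phenotypes$organism[phenotypes$phenotype == "positive"]
  if (!all(positives %in% grouping$organism)) {
    abort_param("`grouping` must cover every positive organism")
  }
  groups <- split(grouping$organism, grouping$group)
  lo <- as.integer(min(subset_size_range))
  hi <- as.integer(max(subset_size_range))
  if (length(groups) < lo) {
    abort_param(sprintf(
      "only %d groups available but the minimum subset size is %d",
      length(groups), lo
    ))
  }
  hi <- min(hi, length(groups))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    subset <- NULL
    for (attempt in 1:100) {
      reps <- vapply(groups, function(g) g[sample.int(length(g), 1)],
                     character(1))
      size <- sample(lo:hi, 1)
      cand <- sample(reps, size)
      if (any(cand %in% positives)) {
        subset <- sort_c(cand)
        break
      }
    }
    if (is.null(subset)) {
      abort_param("could not draw a subset containing a positive organism")
    }
    sub_ann <- phenotypes[phenotypes$organism %in% subset, , drop = FALSE]
    sub_links <- links[links$organism %in% subset, , drop = FALSE]
    sub_nodes <- if (!is.null(nodes)) {
      nodes[nodes$organism %in% subset, , drop = FALSE]
    }
    cfg <- pipeline_config(
      links = sub_links, phenotypes = sub_ann, nodes = sub_nodes,
      distances = distances, edge_threshold = edge_threshold,
      pairs = pairs, auto_params = is.null(pairs),
      p_threshold = p_threshold, min_cogs = min_cogs
    )
    mods <- suppressWarnings(run_pipeline(cfg))
    ranked <- mods[order_c(
      mods$p_value,
      -ifelse(is.na(mods$phylo_score), -Inf, mods$phylo_score),
      module_key(mods)
    ), , drop = FALSE]
    top <- head(vapply(ranked$cogs, paste, character(1), collapse = ";"),
                top_n)
    trials[[tr]] <- list(organisms = subset, n_modules = nrow(mods),
                         top = top)
  }

  pairs_idx <- if (n_trials >= 2) utils::combn(n_trials, 2) else {
    matrix(integer(0), nrow = 2)
  }
  overlaps <- tibble(
    trial_i = as.integer(pairs_idx[1, ]),
    trial_j = as.integer(pairs_idx[2, ]),
    overlap = vapply(seq_len(ncol(pairs_idx)), function(k) {
      a <- trials[[pairs_idx[1, k]]]$top
      b <- trials[[pairs_idx[2, k]]]$top
      if (length(a) == 0 && length(b) == 0) return(1)
      length(intersect(a, b)) / max(length(a), length(b))
    }, numeric(1))
  )
  mean_overlap <- if (nrow(overlaps) == 0) 1 else mean(overlaps$overlap)
  structure(
    list(
      trials = tibble(
        trial = seq_len(n_trials),
        organisms = lapply(trials, `[[`, "organisms"),
        n_modules = vapply(trials, `[[`, integer(1), "n_modules"),
        top = lapply(trials, `[[`, "top")
      ),
      overlaps = overlaps,
      mean_overlap = mean_overlap
    ),
    class = "robustness_report"
  )
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> %d trial(s), mean top-list overlap %.3f\n",
    nrow(x$trials), x$mean_overlap
  ))
  invisible(x)
}

# module table serialisation -------------------------------------------------

join_set <- function(x) paste(sort_c(x), collapse = ";")

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x)) # %.17g round-trips doubles
}

#' Write / read a module table
#'
#' `write_modules()` writes the canonical TSV (columns `cog_set`,
#' `positive_orgs`, `negative_orgs`, `alpha_count`, `beta_count`,
#' `p_value`, `phylo_score`; set fields semicolon-joined and sorted;
#' unset scores rendered `NA`) plus a JSON mirror next to it (same stem,
#' `.json`). `read_modules()` inverts it exactly:
#' `read_modules(write_modules(x))` reproduces `x`.
#'
#' @param modules An `ab_modules` tibble.
#' @param path TSV output path.
#' @return `write_modules()`: invisibly, the paths written;
#'   `read_modules()`: an `ab_modules` tibble.
#' @export
write_modules <- function(modules, path) {
  check_columns(
    modules,
    c("cogs", "positive_orgs", "negative_orgs", "alpha_count", "beta_count",
      "p_value", "phylo_score"),
    "modules"
  )
  df <- tibble(
    cog_set = vapply(modules$cogs, join_set, character(1)),
    positive_orgs = vapply(modules$positive_orgs, join_set, character(1)),
    negative_orgs = vapply(modules$negative_orgs, join_set, character(1)),
    alpha_count = modules$alpha_count,
    beta_count = modules$beta_count,
    p_value = fmt_num(modules$p_value),
    phylo_score = fmt_num(modules$phylo_score)
  )
  lines <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(unname(as.list(df)), sep = "\t"))
  )
  writeLines(lines, path)
  json_path <- sub("\\.[^.]*$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  recs <- lapply(seq_len(nrow(modules)), function(i) {
    list(
      cog_set = modules$cogs[[i]],
      positive_orgs = modules$positive_orgs[[i]],
      negative_orgs = modules$negative_orgs[[i]],
      alpha_count = modules$alpha_count[i],
      beta_count = modules$beta_count[i],
      p_value = modules$p_value[i],
      phylo_score = modules$phylo_score[i]
    )
  })
  jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = path, json = json_path))
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  expected <- c("cog_set", "positive_orgs", "negative_orgs", "alpha_count",
                "beta_count", "p_value", "phylo_score")
  if (length(lines) == 0 ||
      !identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]], expected)) {
    abort_parse(sprintf("'%s' line 1: unexpected module table header", path))
  }
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 6 && endsWith(body[i], "\t")) f <- c(f, "")
    if (length(f) != 7) {
      abort_parse(sprintf(
        "'%s' line %d: expected 7 tab-separated fields, found %d",
        path, i + 1, length(f)
      ))
    }
    counts <- suppressWarnings(as.integer(f[4:5]))
    nums <- suppressWarnings(as.numeric(ifelse(f[6:7] == "NA", NA, f[6:7])))
    if (anyNA(counts) ||
        (any(is.na(nums) & f[6:7] != "NA"))) {
      abort_parse(sprintf("'%s' line %d: malformed numeric field", path, i + 1))
    }
    list(
      cogs = split_set(f[1]), positive_orgs = split_set(f[2]),
      negative_orgs = split_set(f[3]), alpha_count = counts[1],
      beta_count = counts[2], p_value = nums[1], phylo_score = nums[2]
    )
  })
  modules <- tibble(
    cogs = lapply(rows, `[[`, "cogs"),
    positive_orgs = lapply(rows, `[[`, "positive_orgs"),
    negative_orgs = lapply(rows, `[[`, "negative_orgs"),
    n_cogs = vapply(rows, function(r) length(r$cogs), integer(1)),
    alpha_count = vapply(rows, `[[`, integer(1), "alpha_count"),
    beta_count = vapply(rows, `[[`, integer(1), "beta_count"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    phylo_score = vapply(rows, `[[`, numeric(1), "phylo_score")
  )
  new_ab_modules(modules)
}
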