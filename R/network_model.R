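#' Build a two-typed, divided network from per-organism association networks
#'
#' Combines per-organism COG-level functional association networks into a
#' single graph whose vertex set is partitioned into one division per
#' organism, each division labelled by the organism's phenotype (positive =
#' phenotype-expressing, negative = non-expressing). A vertex is an
#' (organism, COG) pair. Three edge kinds are laid down:
#'
#' * **intra-organismal** edges: the input functional associations with
#'   `combined_score >= edge_threshold`, within one division;
#' * **orthology** inter-organismal edges: `(A, c)`--`(B, c)` for every pair
#'   of distinct organisms that both contain COG `c` (orthology is COG
#'   identity, no score condition);
#' * **conserved-association** inter-organismal edges: `(A, c1)`--`(B, c2)`
#'   with `c1 != c2` exists if and only if the association `c1`--`c2`
#'   survives the threshold in *both* `A` and `B`.
#'
#' Under this construction a functional module conserved across a set of
#' organisms appears as a single maximal clique of the divided network, so
#' cross-organism module comparison reduces to clique enumeration.
#'
#' @param links Data frame of intra-organismal associations with columns
#'   `organism`, `node1`, `node2`, `combined_score` (integer confidence,
#'   0--999, STRING-style). Edges are undirected; reversed duplicates are
#'   merged keeping the maximum score; self-loops are dropped.
#' @param annotations Data frame with columns `organism` and `phenotype`
#'   (`"positive"` or `"negative"`), one row per organism. Must cover every
#'   organism appearing in `links`.
#' @param edge_threshold Integer in `[0, 999]`; intra edges strictly below
#'   it are discarded (applied before inter-edge construction).
#' @param nodes Optional data frame with columns `organism`, `cog` declaring
#'   COG presence beyond edge endpoints (isolated COGs are kept as vertices
#'   and can join orthology-only cliques).
#'
#' @return A `divided_network` object: a list with tibbles `vertices`
#'   (`vid`, `organism`, `cog`, `phenotype`), `organisms`, `intra_edges`,
#'   `inter_edges` (with `kind` in `orthology` / `conserved_association`),
#'   an adjacency list `adj`, and the `edge_threshold` used.
#'
#' @examples
#' links <- tibble::tibble(
#'   organism = c("A", "B"), node1 = "c1", node2 = "c2",
#'   combined_score = c(900L, 900L)
#' )
#' ann <- tibble::tibble(organism = c("A", "B"), phenotype = "positive")
#' net <- build_divided_network(links, ann, edge_threshold = 800)
#' glance(net)
#' @export
build_divided_network <- function(links, annotations, edge_threshold,
                                  nodes = NULL) {
  annotations <- validate_annotations(annotations)
  if (!is.numeric(edge_threshold) || length(edge_threshold) != 1 ||
      is.na(edge_threshold) || edge_threshold < 0 || edge_threshold > 999) {
    abort_param("`edge_threshold` must be a single integer in [0, 999]")
  }
  edge_threshold <- as.integer(edge_threshold)

  links <- normalise_links(links)
  link_orgs <- unique(links$organism)
  unknown <- setdiff(link_orgs, annotations$organism)
  if (length(unknown) > 0) {
    abort_config(sprintf(
      "organism(s) in `links` missing from `annotations`: %s",
      paste(sort_c(unknown), collapse = ", ")
    ))
  }
  if (!is.null(nodes)) {
    check_columns(nodes, c("organism", "cog"), "nodes")
    unknown <- setdiff(unique(nodes$organism), annotations$organism)
    if (length(unknown) > 0) {
      abort_config(sprintf(
        "organism(s) in `nodes` missing from `annotations`: %s",
        paste(sort_c(unknown), collapse = ", ")
      ))
    }
  }

  # COG presence per organism: edge endpoints (any score) plus declared nodes
  presence <- dplyr::bind_rows(
    tibble(organism = links$organism, cog = links$node1),
    tibble(organism = links$organism, cog = links$node2),
    if (!is.null(nodes)) {
      tibble(organism = as.character(nodes$organism), cog = as.character(nodes$cog))
    }
  )
  presence <- distinct(presence)

  vertices <- presence[order_c(presence$organism, presence$cog), , drop = FALSE]
  vertices <- as_tibble(vertices)
  vertices$vid <- seq_len(nrow(vertices))
  vertices <- left_join(vertices, annotations, by = "organism")
  vertices <- vertices[, c("vid", "organism", "cog", "phenotype")]

  intra <- links[links$combined_score >= edge_threshold, , drop = FALSE]
  intra <- tibble(
    organism = intra$organism,
    cog1 = pmin(intra$node1, intra$node2),
    cog2 = pmax(intra$node1, intra$node2),
    score = intra$combined_score
  )
  intra <- intra[order_c(intra$organism, intra$cog1, intra$cog2), , drop = FALSE]

  # orthology: all organism pairs sharing a COG
  orth <- inner_join(
    vertices[, c("organism", "cog")], vertices[, c("organism", "cog")],
    by = "cog", suffix = c("1", "2"), relationship = "many-to-many"
  )
  orth <- orth[orth$organism1 < orth$organism2, , drop = FALSE]
  orth <- tibble(
    organism1 = orth$organism1, cog1 = orth$cog,
    organism2 = orth$organism2, cog2 = orth$cog,
    kind = "orthology"
  )

  # conserved association: intra edge (c1, c2) present in both organisms
  # yields the two cross edges (A,c1)-(B,c2) and (A,c2)-(B,c1)
  ij <- inner_join(
    intra[, c("organism", "cog1", "cog2")],
    intra[, c("organism", "cog1", "cog2")],
    by = c("cog1", "cog2"), suffix = c("1", "2"),
    relationship = "many-to-many"
  )
  ij <- ij[ij$organism1 < ij$organism2, , drop = FALSE]
  cons <- dplyr::bind_rows(
    tibble(
      organism1 = ij$organism1, cog1 = ij$cog1,
      organism2 = ij$organism2, cog2 = ij$cog2
    ),
    tibble(
      organism1 = ij$organism1, cog1 = ij$cog2,
      organism2 = ij$organism2, cog2 = ij$cog1
    )
  )
  cons$kind <- "conserved_association"

  inter <- dplyr::bind_rows(orth, cons)
  inter <- inter[
    order_c(inter$organism1, inter$cog1, inter$organism2, inter$cog2),
    , drop = FALSE
  ]

  net <- structure(
    list(
      vertices = vertices,
      organisms = annotations,
      intra_edges = intra,
      inter_edges = inter,
      edge_threshold = edge_threshold
    ),
    class = "divided_network"
  )
  net$adj <- build_adjacency(net)
  net
}

validate_annotations <- function(annotations) {
  check_columns(annotations, c("organism", "phenotype"), "annotations")
  annotations <- tibble(
    organism = as.character(annotations$organism),
    phenotype = as.character(annotations$phenotype)
  )
  if (anyDuplicated(annotations$organism)) {
    dup <- unique(annotations$organism[duplicated(annotations$organism)])
    abort_config(sprintf(
      "duplicate organism_id in annotations: %s", paste(dup, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(annotations$phenotype), c("positive", "negative"))
  if (length(bad) > 0) {
    abort_config(sprintf(
      "phenotype must be 'positive' or 'negative'; got: %s",
      paste(bad, collapse = ", ")
    ))
  }
  annotations[order_c(annotations$organism), , drop = FALSE]
}

# undirected normal form: character endpoints, no self loops, reversed
# duplicates merged keeping the maximum combined score
normalise_links <- function(links) {
  check_columns(links, c("organism", "node1", "node2", "combined_score"),
                "links")
  score <- links$combined_score
  if (!is.numeric(score) || anyNA(suppressWarnings(as.numeric(score)))) {
    abort_parse("`combined_score` must be numeric with no missing values")
  }
  if (any(score < 0 | score > 999) || any(score != floor(score))) {
    abort_parse("`combined_score` values must be integers in [0, 999]")
  }
  out <- tibble(
    organism = as.character(links$organism),
    node1 = pmin(as.character(links$node1), as.character(links$node2)),
    node2 = pmax(as.character(links$node1), as.character(links$node2)),
    combined_score = as.integer(score)
  )
  out <- out[out$node1 != out$node2, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  out <- group_by(out, .data$organism, .data$node1, .data$node2)
  out <- summarise(out, combined_score = max(.data$combined_score),
                   .groups = "drop")
  out
}

vertex_key <- function(organism, cog) paste(organism, cog, sep = "\r")

# adjacency list (sorted integer neighbour vectors, 1-based vids)
build_adjacency <- function(net) {
  v <- net$vertices
  key <- vertex_key(v$organism, v$cog)
  lookup <- function(org, cog) match(vertex_key(org, cog), key)
  from <- c(
    lookup(net$intra_edges$organism, net$intra_edges$cog1),
    lookup(net$inter_edges$organism1, net$inter_edges$cog1)
  )
  to <- c(
    lookup(net$intra_edges$organism, net$intra_edges$cog2),
    lookup(net$inter_edges$organism2, net$inter_edges$cog2)
  )
  n <- nrow(v)
  adj <- vector("list", n)
  both <- split(c(to, from), factor(c(from, to), levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- sort.int(unique(both[[i]]))
  adj
}

#' Count organisms of one phenotype touched by a vertex set
#'
#' The type-count `c(S, t)`: the number of organisms of phenotype `t` that
#' contribute at least one vertex to `S`. Because every clique of the
#' divided network contains either a full per-organism sub-clique or nothing
#' from each organism, touching an organism with a single vertex is
#' sufficient evidence that the organism carries the module.
#'
#' @param network A `divided_network`.
#' @param vertex_set Either an integer vector of vertex ids (`vid`) or a
#'   data frame with columns `organism`, `cog`.
#' @param type `"positive"` or `"negative"`.
#' @return A non-negative integer count.
#' @examples
#' links <- tibble::tibble(
#'   organism = "A", node1 = "c1", node2 = "c2", combined_score = 900L
#' )
#' ann <- tibble::tibble(organism = "A", phenotype = "positive")
#' net <- build_divided_network(links, ann, 800)
#' type_count(net, net$vertices, "positive")
#' @export
type_count <- function(network, vertex_set, type = c("positive", "negative")) {
  stopifnot(inherits(network, "divided_network"))
  type <- match.arg(type)
  v <- network$vertices
  if (is.data.frame(vertex_set)) {
    check_columns(vertex_set, c("organism", "cog"), "vertex_set")
    vids <- match(
      vertex_key(vertex_set$organism, vertex_set$cog),
      vertex_key(v$organism, v$cog)
    )
  } else {
    vids <- as.integer(vertex_set)
    vids[vids < 1 | vids > nrow(v)] <- NA_integer_
  }
  if (anyNA(vids)) {
    abort_input("`vertex_set` contains vertices not present in the network")
  }
  orgs <- unique(v$organism[vids])
  sum(network$organisms$phenotype[match(orgs, network$organisms$organism)] == type)
}

#' Project a protein-level network onto COGs
#'
#' Replaces proteins by their cluster of orthologous groups (COG) so that
#' vertex identity is shared across organisms. Protein--protein edges map to
#' COG--COG edges; when several protein pairs collapse onto the same COG
#' pair the maximum combined score is kept, and pairs collapsing onto a
#' single COG are dropped (no self-loops). Unmapped proteins are dropped and
#' reported.
#'
#' @param protein_edges Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (integers in 0--999).
#' @param mapping Data frame with columns `protein`, `cog`; may be partial.
#' @param organism Organism identifier attached to the projected network.
#' @return A list of class `cog_projection` with elements `links` (tibble
#'   `organism`, `node1`, `node2`, `combined_score`), `cogs` (tibble
#'   `organism`, `cog`: every COG hit by a mapped protein, including
#'   edge-less ones), and `unmapped` (character vector of dropped proteins).
#' @export
project_proteins_to_cogs <- function(protein_edges, mapping, organism) {
  check_columns(protein_edges, c("protein1", "protein2", "combined_score"),
                "protein_edges")
  check_columns(mapping, c("protein", "cog"), "mapping")
  score <- suppressWarnings(as.numeric(protein_edges$combined_score))
  if (anyNA(score) || any(score < 0 | score > 999) ||
      any(score != floor(score))) {
    abort_parse("`combined_score` values must be integers in [0, 999]")
  }
  map <- distinct(tibble(
    protein = as.character(mapping$protein),
    cog = as.character(mapping$cog)
  ))
  if (anyDuplicated(map$protein)) {
    abort_config("`mapping` assigns multiple COGs to one protein")
  }
  proteins <- unique(c(
    as.character(protein_edges$protein1),
    as.character(protein_edges$protein2)
  ))
  cog_of <- map$cog[match(proteins, map$protein)]
  unmapped <- sort_c(proteins[is.na(cog_of)])

  c1 <- map$cog[match(as.character(protein_edges$protein1), map$protein)]
  c2 <- map$cog[match(as.character(protein_edges$protein2), map$protein)]
  keep <- !is.na(c1) & !is.na(c2) & c1 != c2
  links <- tibble(
    organism = as.character(organism),
    node1 = pmin(c1[keep], c2[keep]),
    node2 = pmax(c1[keep], c2[keep]),
    combined_score = as.integer(score[keep])
  )
  if (nrow(links) > 0) {
    links <- group_by(links, .data$organism, .data$node1, .data$node2)
    links <- summarise(links, combined_score = max(.data$combined_score),
                       .groups = "drop")
  }
  cogs <- tibble(
    organism = as.character(organism),
    cog = sort_c(unique(stats::na.omit(cog_of)))
  )
  structure(
    list(links = links, cogs = cogs, unmapped = unmapped),
    class = "cog_projection"
  )
}

#' @export
print.cog_projection <- function(x, ...) {
  cat(sprintf(
    "<cog_projection> %s: %d COGs, %d COG-COG edges, %d unmapped proteins\n",
    unique(c(x$links$organism, x$cogs$organism))[1] %||% "?",
    nrow(x$cogs), nrow(x$links), length(x$unmapped)
  ))
  invisible(x)
}

#' @export
print.divided_network <- function(x, ...) {
  ph <- table(factor(x$organisms$phenotype, c("positive", "negative")))
  cat(sprintf(
    paste0(
      "<divided_network> %d organisms (%d positive, %d negative), ",
      "%d vertices\n  intra edges: %d (threshold %d), inter edges: %d ",
      "(%d orthology, %d conserved)\n"
    ),
    nrow(x$organisms), ph[["positive"]], ph[["negative"]], nrow(x$vertices),
    nrow(x$intra_edges), x$edge_threshold, nrow(x$inter_edges),
    sum(x$inter_edges$kind == "orthology"),
    sum(x$inter_edges$kind == "conserved_association")
  ))
  invisible(x)
}

#' @rdname build_divided_network
#' @param x A `divided_network`.
#' @param ... Unused.
#' @method glance divided_network
#' @export
glance.divided_network <- function(x, ...) {
  tibble(
    n_organisms = nrow(x$organisms),
    n_positive = sum(x$organisms$phenotype == "positive"),
    n_negative = sum(x$organisms$phenotype == "negative"),
    n_vertices = nrow(x$vertices),
    n_intra_edges = nrow(x$intra_edges),
    n_inter_edges = nrow(x$inter_edges),
    edge_threshold = x$edge_threshold
  )
}

#' @rdname build_divided_network
#' @method tidy divided_network
#' @export
tidy.divided_network <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      organism1 = x$intra_edges$organism, cog1 = x$intra_edges$cog1,
      organism2 = x$intra_edges$organism, cog2 = x$intra_edges$cog2,
      kind = "intra", score = x$intra_edges$score
    ),
    tibble(
      organism1 = x$inter_edges$organism1, cog1 = x$inter_edges$cog1,
      organism2 = x$inter_edges$organism2, cog2 = x$inter_edges$cog2,
      kind = x$inter_edges$kind, score = NA_integer_
    )
  )
}
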