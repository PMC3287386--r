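#' Validate and normalise an organism distance matrix
#'
#' Accepts a square numeric matrix with organism ids as dimnames (or a data
#' frame whose first column holds the ids). Checks non-negativity, a
#' (numerically) zero diagonal, and symmetry: entries whose asymmetry is
#' within 1e-9 relative tolerance are symmetrised by averaging; larger
#' asymmetries are a hard error.
#'
#' @param x Matrix or data frame as described.
#' @return A symmetric numeric matrix with zero diagonal and organism ids
#'   as row and column names.
#' @export
as_phylo_dist <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    if (is.null(colnames(m)) || !setequal(colnames(m), ids)) {
      colnames(m) <- ids
    }
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x)) {
    abort_input("distance matrix must be a square numeric matrix")
  }
  if (is.null(rownames(x))) {
    abort_input("distance matrix must carry organism ids as dimnames")
  }
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!setequal(colnames(x), rownames(x))) {
    abort_input("distance matrix row and column organism ids differ")
  }
  x <- x[, rownames(x), drop = FALSE] # align column order to rows
  if (anyNA(x) || any(x < 0)) {
    abort_input("distances must be non-negative and non-missing")
  }
  scale <- max(abs(x), 1)
  if (any(abs(diag(x)) > 1e-9 * scale)) {
    abort_input("distance matrix diagonal must be zero")
  }
  asym <- abs(x - t(x))
  if (any(asym > 1e-9 * pmax(abs(x) + abs(t(x)), 1))) {
    abort_input("distance matrix is not symmetric (beyond 1e-9 tolerance)")
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x
}

#' Phylogenetic diversity score of a module
#'
#' Scores how phylogenetically spread the organisms carrying a module are,
#' rewarding conservation across *distantly related* phenotype-expressing
#' organisms. With `OrgP` / `OrgN` the positive / negative carriers and
#' `d(i, j)` the organism distance:
#'
#' \deqn{PP = \sum_{i \in OrgP} \sum_{j \in OrgP} d(i,j), \quad
#'       PN = \sum_{i \in OrgP} \sum_{j \in OrgN} d(i,j), \quad
#'       NN = \sum_{i \in OrgN} \sum_{j \in OrgN} d(i,j)}
#' \deqn{S_p = (PP - PN - NN) / (PP + PN + NN)}
#'
#' The sums run over *ordered* pairs exactly as written: `PP` and `NN`
#' visit each unordered pair twice (the diagonal contributes zero) while
#' `PN` visits each cross pair once. This asymmetry is part of the score's
#' definition and is implemented as printed, not "corrected". The score
#' lies in `[-1, 1]`: `+1` when only positive carriers at positive
#' distances are involved, `-1` when no positive pair spread exists, and it
#' is invariant to rescaling all distances.
#'
#' When every pairwise distance involved is zero (e.g. a module carried by
#' a single organism) the score is undefined; `0` is returned as a neutral
#' sentinel with a warning.
#'
#' @param positive_orgs,negative_orgs Character vectors of carrier
#'   organism ids (disjoint).
#' @param dm Distance matrix acceptable to [as_phylo_dist()].
#' @return A scalar in `[-1, 1]`.
#' @examples
#' dm <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3,
#'   dimnames = list(c("p1", "p2", "n1"), c("p1", "p2", "n1"))
#' )
#' phylo_score(c("p1", "p2"), "n1", dm) # (4 - 2 - 0) / (4 + 2 + 0) = 1/3
#' @export
phylo_score <- function(positive_orgs, negative_orgs, dm) {
  dm <- as_phylo_dist(dm)
  positive_orgs <- as.character(positive_orgs)
  negative_orgs <- as.character(negative_orgs)
  if (length(intersect(positive_orgs, negative_orgs)) > 0) {
    abort_input("positive and negative carrier sets must be disjoint")
  }
  missing <- setdiff(c(positive_orgs, negative_orgs), rownames(dm))
  if (length(missing) > 0) {
    abort_input(sprintf(
      "organism(s) missing from the distance matrix: %s",
      paste(sort_c(missing), collapse = ", ")
    ))
  }
  pp <- sum(dm[positive_orgs, positive_orgs])
  pn <- sum(dm[positive_orgs, negative_orgs])
  nn <- sum(dm[negative_orgs, negative_orgs])
  denom <- pp + pn + nn
  if (denom == 0) {
    warn(
      "phylogenetic score undefined (all involved distances zero); returning 0",
      class = "abmotif_degenerate_phylo"
    )
    return(0)
  }
  (pp - pn - nn) / denom
}

#' Attach phylogenetic diversity scores to a module table
#'
#' @param modules An `ab_modules` tibble (list-columns `positive_orgs`,
#'   `negative_orgs`).
#' @param dm Distance matrix acceptable to [as_phylo_dist()].
#' @return `modules` with the `phylo_score` column filled.
#' @export
add_phylo_scores <- function(modules, dm) {
  check_columns(modules, c("positive_orgs", "negative_orgs"), "modules")
  dm <- as_phylo_dist(dm)
  modules$phylo_score <- vapply(seq_len(nrow(modules)), function(i) {
    phylo_score(modules$positive_orgs[[i]], modules$negative_orgs[[i]], dm)
  }, numeric(1))
  modules
}

#' Read an organism distance matrix from disk
#'
#' Accepts either a labelled TSV (header row of organism ids, first column
#' of organism ids, square numeric body) or a PHYLIP-style square distance
#' matrix (first line the organism count, then one labelled row per
#' organism).
#'
#' @param path File path.
#' @return A validated symmetric matrix (see [as_phylo_dist()]).
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'", path))
  first <- readLines(path, n = 1L)
  tok <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (length(tok) == 1 && grepl("^[0-9]+$", tok)) {
    # PHYLIP square
    n <- as.integer(tok)
    body <- read.table(path, skip = 1, header = FALSE,
                       stringsAsFactors = FALSE)
    if (nrow(body) != n || ncol(body) != n + 1) {
      abort_parse(sprintf(
        "PHYLIP matrix in '%s' does not match its declared size %d", path, n
      ))
    }
    m <- as.matrix(body[, -1])
    rownames(m) <- colnames(m) <- as.character(body[[1]])
  } else {
    body <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE)
    m <- as.matrix(body[, -1, drop = FALSE])
    rownames(m) <- as.character(body[[1]])
  }
  storage.mode(m) <- "double"
  as_phylo_dist(m)
}
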