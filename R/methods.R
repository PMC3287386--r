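#' @export
print.ab_modules <- function(x, ...) {
  cat(sprintf("<ab_modules> %d module(s)\n", nrow(x)))
  NextMethod()
}

#' Tidy a module table into one row per (module, COG)
#'
#' @param x An `ab_modules` tibble.
#' @param ... Unused.
#' @return A long tibble with columns `module`, `cog`, `alpha_count`,
#'   `beta_count`, `p_value`, `phylo_score`.
#' @method tidy ab_modules
#' @export
tidy.ab_modules <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(
      module = integer(), cog = character(), alpha_count = integer(),
      beta_count = integer(), p_value = double(), phylo_score = double()
    ))
  }
  long <- tibble(
    module = rep(seq_len(nrow(x)), lengths(x$cogs)),
    cog = unlist(x$cogs)
  )
  info <- tibble(
    module = seq_len(nrow(x)),
    alpha_count = x$alpha_count, beta_count = x$beta_count,
    p_value = x$p_value, phylo_score = x$phylo_score
  )
  left_join(long, info, by = "module")
}

#' Summarise a module table
#'
#' @param x An `ab_modules` tibble.
#' @param ... Unused.
#' @return A one-row tibble: module count, distinct COGs, size range, and
#'   the smallest p-value.
#' @method glance ab_modules
#' @export
glance.ab_modules <- function(x, ...) {
  tibble(
    n_modules = nrow(x),
    n_distinct_cogs = n_distinct(unlist(x$cogs)),
    max_cogs = if (nrow(x)) max(x$n_cogs) else NA_integer_,
    min_p_value = if (nrow(x) && !all(is.na(x$p_value))) {
      min(x$p_value, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Heatmap of clique counts over the (alpha, beta) grid
#'
#' @param object An `ab_grid` from [scan_parameter_grid()].
#' @param ... Unused.
#' @return A ggplot: beta on the x axis, alpha on the y axis, log-scaled
#'   fill by clique count.
#' @method autoplot ab_grid
#' @export
autoplot.ab_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$beta, y = .data$alpha, fill = log10(.data$n_cliques + 1)
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_cliques), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "log10(count + 1)") +
    ggplot2::labs(
      x = expression(beta), y = expression(alpha),
      title = "(alpha, beta)-clique counts"
    ) +
    ggplot2::theme_minimal()
}

#' Search-tree size under the three bound modes
#'
#' @param object An `ab_benchmark` from [benchmark_bounds()].
#' @param ... Unused.
#' @return A ggplot bar chart of nodes expanded per bound mode.
#' @method autoplot ab_benchmark
#' @export
autoplot.ab_benchmark <- function(object, ...) {
  df <- as_tibble(object)
  df$bound_mode <- factor(df$bound_mode,
                          c("none", "beta_only", "alpha_beta"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bound_mode, y = .data$nodes)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "bound mode", y = "search-tree nodes",
      title = "Pruning effect of the search bounds"
    ) +
    ggplot2::theme_minimal()
}

#' Accuracy and network size along the threshold ladder
#'
#' @param object A `threshold_report` from [select_edge_threshold()].
#' @param ... Unused.
#' @return A ggplot of validation accuracy against the edge threshold,
#'   with the selected threshold marked.
#' @method autoplot threshold_report
#' @export
autoplot.threshold_report <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "edge threshold (descending)", y = "validation accuracy",
      title = "Edge-threshold selection"
    ) +
    ggplot2::theme_minimal()
}
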