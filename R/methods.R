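#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the gating tree
#'
#' One row per tree node with the split bookkeeping: the dimension pair
#' chosen, boundary score, balance fraction P, kernel widenings used, and
#' for leaves the phenotype id and heuristic label.
#'
#' @param x An `epp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per node.
#' @export
tidy.epp_fit <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(nd) {
    tibble::tibble(
      node = nd$id, parent = nd$parent, depth = nd$depth,
      n_events = nd$n_events, is_leaf = nd$is_leaf,
      phenotype = nd$phenotype,
      dim_x = if (nd$is_leaf) NA_character_ else nd$pair_names[1],
      dim_y = if (nd$is_leaf) NA_character_ else nd$pair_names[2],
      kernel_sd = if (nd$is_leaf) NA_real_ else nd$kernel_sd,
      widening_passes = if (nd$is_leaf) NA_integer_ else nd$passes,
      raw_score = if (nd$is_leaf) NA_real_ else nd$raw_score,
      adjusted_score = if (nd$is_leaf) NA_real_ else nd$adjusted_score,
      P = if (nd$is_leaf) NA_real_ else nd$P,
      label = if (nd$is_leaf) leaf_label(x, nd) else NA_character_)
  })
}

#' One-line summary of a gating run
#'
#' @param x An `epp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: events, censored events, node count, leaf
#'   (algorithmic phenotype) count, tree depth.
#' @export
glance.epp_fit <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    n_censored = n_censored(x$events),
    n_nodes = length(x$nodes),
    n_phenotypes = x$n_leaves,
    max_depth = max(vapply(x$nodes, `[[`, 0L, "depth")))
}

#' Plot a split or the gating tree
#'
#' `type = "gates"` shows the two-dimensional density of a split node with
#' the two child gate polygons overlaid; `type = "tree"` draws the gating
#' tree with node sizes and split dimensions.
#'
#' @param object An `epp_fit`.
#' @param type `"gates"` or `"tree"`.
#' @param node Node id for `type = "gates"` (default 1, the root).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epp_fit <- function(object, type = c("gates", "tree"), node = 1L, ...) {
  type <- match.arg(type)
  if (type == "gates") return(plot_gates(object, node))
  plot_tree(object)
}

#' @rdname autoplot.epp_fit
#' @param fit An `epp_fit`.
#' @export
plot_gates <- function(fit, node = 1L) {
  nd <- fit$nodes[[node]]
  if (nd$is_leaf) stop("node ", node, " is a leaf; nothing to plot")
  X <- as.matrix(fit$events[, fit$pheno, drop = FALSE])
  x <- X[nd$rows, nd$pair[1]]; y <- X[nd$rows, nd$pair[2]]
  df <- tibble::tibble(x = x, y = y)
  polys <- dplyr::bind_rows(
    tibble::tibble(x = nd$gate_left[, 1], y = nd$gate_left[, 2], side = "left"),
    tibble::tibble(x = nd$gate_right[, 1], y = nd$gate_right[, 2], side = "right"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_bin2d(bins = 128, show.legend = FALSE) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::geom_path(data = polys,
                       ggplot2::aes(group = .data$side, colour = .data$side),
                       linewidth = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = nd$pair_names[1], y = nd$pair_names[2],
                  title = sprintf("node %d: %s x %s (P = %.2f)",
                                  node, nd$pair_names[1], nd$pair_names[2],
                                  nd$P)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.epp_fit
#' @export
plot_tree <- function(fit) {
  td <- tidy(fit)
  # simple layout: leaves evenly spaced, internal nodes over their children
  xs <- numeric(nrow(td))
  leaf_ids <- td$node[td$is_leaf]
  xs[match(leaf_ids, td$node)] <- order(order(match(leaf_ids, td$node)))
  for (dpt in sort(unique(td$depth), decreasing = TRUE)) {
    for (i in which(td$depth == dpt & !td$is_leaf)) {
      kids <- which(td$parent == td$node[i])
      xs[i] <- mean(xs[kids])
    }
  }
  td$x <- xs
  seg <- dplyr::inner_join(
    dplyr::select(td, parent = "node", px = "x", pdepth = "depth"),
    dplyr::select(td, "parent", cx = "x", cdepth = "depth"),
    by = "parent")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = -.data$depth)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = -.data$pdepth,
                                       xend = .data$cx, yend = -.data$cdepth),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_events,
                                     colour = .data$is_leaf),
                        show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$is_leaf, paste0("#", .data$phenotype),
                     paste(.data$dim_x, .data$dim_y, sep = "×"))),
      vjust = -1, size = 3) +
    ggplot2::labs(x = NULL, y = "depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
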