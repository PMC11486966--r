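#' Plot a clone tree
#'
#' Rectangular cladogram with branch lengths equal to event counts; taxa
#' are labeled at their nodes (internal taxa included).
#'
#' @param object A `clone_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_tree <- function(object, ...) {
  depths <- node_depths(object)
  nodes <- object$nodes
  # leaf order by depth-first traversal
  kids <- split(nodes$node[!is.na(nodes$parent)],
                nodes$parent[!is.na(nodes$parent)])
  y <- setNames(rep(NA_real_, nrow(nodes)), nodes$node)
  counter <- 0
  assign_y <- function(n) {
    ch <- kids[[as.character(n)]]
    if (is.null(ch)) {
      counter <<- counter + 1
      y[as.character(n)] <<- counter
    } else {
      for (c in ch) assign_y(c)
      y[as.character(n)] <<- mean(y[as.character(ch)])
    }
  }
  assign_y(tree_root(object))
  df <- tibble(
    node = nodes$node,
    parent = nodes$parent,
    x = unname(depths[as.character(nodes$node)]),
    y = unname(y[as.character(nodes$node)])
  )
  seg <- df %>%
    filter(!is.na(.data$parent)) %>%
    left_join(df %>% select(parent_node = "node", px = "x", py = "y"),
              by = c("parent" = "parent_node"))
  lab <- object$taxa %>%
    left_join(df, by = "node")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$px, yend = .data$y),
                          linewidth = 0.4) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$y,
                                       xend = .data$x, yend = .data$y),
                          linewidth = 0.4) +
    ggplot2::geom_point(data = lab, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$taxon),
                       hjust = -0.2, vjust = -0.4, size = 3) +
    ggplot2::labs(x = "events from root", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Heat map of grouped clone sizes
#'
#' @param object An `event_groups` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_groups <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$event,
                                 fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "MCF") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot subclone territories
#'
#' Draws each territory as a circle of the computed area over the biopsy
#' layout.
#'
#' @param territories Output of [place_territories()].
#' @param layout Optional biopsy layout drawn as dashed outlines.
#' @return A ggplot object.
#' @export
plot_territories <- function(territories, layout = NULL) {
  circle <- function(x, y, r, id) {
    a <- seq(0, 2 * pi, length.out = 60)
    tibble(x = x + r * cos(a), y = y + r * sin(a), id = id)
  }
  polys <- bind_rows(pmap(list(territories$x_mm, territories$y_mm,
                               territories$radius_mm,
                               territories$subclone), circle))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$id),
                          alpha = 0.5, color = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "subclone") +
    ggplot2::theme_minimal()
  if (!is.null(layout)) {
    outlines <- bind_rows(pmap(list(layout$x_mm, layout$y_mm,
                                    sqrt(layout$area_mm2 / pi),
                                    layout$sample_id), circle))
    p <- p + ggplot2::geom_path(data = outlines,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             group = .data$id),
                                linetype = "dashed", color = "grey50")
  }
  p
}

#' Plot clone dynamics over timepoints
#'
#' Stacked area chart (fishplot-style) of clone fractions from
#' [clone_dynamics()].
#'
#' @param dynamics Output of [clone_dynamics()].
#' @return A ggplot object.
#' @export
plot_clone_dynamics <- function(dynamics) {
  dynamics %>%
    mutate(timepoint = factor(.data$timepoint,
                              levels = unique(.data$timepoint))) %>%
    ggplot2::ggplot(ggplot2::aes(x = as.integer(.data$timepoint),
                                 y = .data$fraction, fill = .data$clone)) +
    ggplot2::geom_area(position = "stack", color = "grey20",
                       linewidth = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_along(unique(dynamics$timepoint)),
                                labels = unique(dynamics$timepoint)) +
    ggplot2::labs(x = NULL, y = "clone fraction") +
    ggplot2::theme_minimal()
}
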