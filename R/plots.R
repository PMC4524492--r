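# ggplot2 displays for the main result types.

#' Plot a shared gene-pair matrix
#'
#' Tile display of pair presence (filled), absence (empty) and
#' missing-gene cells (gray), pairs ordered as given.
#'
#' @param object A `pair_matrix` from [shared_pair_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_matrix
#' @export
autoplot.pair_matrix <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      is.na(.data$state) ~ "gene missing",
      .data$state == 1L ~ "pair present",
      TRUE ~ "pair absent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$pair,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("pair present" = "#2c5aa0",
                                          "pair absent" = "#f0f0f0",
                                          "gene missing" = "#9e9e9e")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot a repeat landscape summary
#'
#' Bar chart of distinct repeat elements per size class.
#'
#' @param object A `repeat_summary` from [mask_and_summarize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeat_summary
#' @export
autoplot.repeat_summary <- function(object, ...) {
  ggplot2::ggplot(object$size_classes,
                  ggplot2::aes(x = .data$size_class, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c5aa0") +
    ggplot2::labs(x = "repeat size class (bp)", y = "distinct elements",
                  subtitle = sprintf("masked %.1f%% of %d bp",
                                     object$masked_percent,
                                     object$genome_length)) +
    ggplot2::theme_minimal()
}

#' Plot the quadripartite architecture of a genome
#'
#' Linear segment view of LSC / IRA / SSC / IRB coordinates.
#'
#' @param object An `ir_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ir_annotation
#' @export
autoplot.ir_annotation <- function(object, ...) {
  df <- tidy.ir_annotation(object)
  df$end_plot <- pmin(df$end, object$genome_length)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end_plot,
                                       y = .data$region, yend = .data$region,
                                       color = .data$region),
                          linewidth = 6) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Plot sidedness indices across taxa
#'
#' @param sidedness Tibble from [sidedness_index()].
#' @return A ggplot object.
#' @export
plot_sidedness <- function(sidedness) {
  ggplot2::ggplot(sidedness,
                  ggplot2::aes(x = stats::reorder(.data$taxon, .data$cs),
                               y = .data$cs)) +
    ggplot2::geom_col(fill = "#2c5aa0") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(C[s])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a Dollo map on its tree
#'
#' Simple segment rendering of the tree with the gain branch and loss
#' branches highlighted.
#'
#' @param map A `dollo_map`.
#' @return A ggplot object.
#' @export
plot_dollo_map <- function(map) {
  tree <- map$tree
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  # leaf y = order; internal y = mean of children; x = depth from root
  depth <- numeric(nn)
  for (e in rev(ape::postorder(tree))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1
  }
  y <- numeric(nn)
  y[seq_len(nt)] <- seq_len(nt)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    kids <- children_of(tree, p)
    y[p] <- mean(y[kids])
  }
  seg <- tibble(node = tree$edge[, 2],
                x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
                y = y[tree$edge[, 2]], yend = y[tree$edge[, 2]],
                vy = y[tree$edge[, 1]])
  seg$event <- dplyr::case_when(seg$node %in% map$loss_nodes ~ "loss",
                                seg$node %in% map$gain_node ~ "gain",
                                TRUE ~ "none")
  labs_df <- tibble(x = depth[seq_len(nt)], y = y[seq_len(nt)],
                    label = tree$tip.label)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$vy, yend = .data$yend),
                          color = "gray60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend,
                                       color = .data$event),
                          linewidth = 1) +
    ggplot2::geom_text(data = labs_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 0, nudge_x = 0.05, size = 2.5) +
    ggplot2::scale_color_manual(values = c(none = "gray40", gain = "#2c7a2c",
                                           loss = "#c0392b")) +
    ggplot2::expand_limits(x = max(depth) * 1.4) +
    ggplot2::labs(x = "depth", y = NULL, color = "event") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
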