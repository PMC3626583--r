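#' @method tidy cucumap_map
#' @export
tidy.cucumap_map <- function(x, ...) {
  as_tibble(x)[, c("marker", "lg", "cM")]
}

#' @method glance cucumap_map
#' @export
glance.cucumap_map <- function(x, ...) {
  per <- as_tibble(x) |>
    group_by(.data$lg) |>
    summarise(len = max(.data$cM), .groups = "drop")
  tibble(n_loci = nrow(x), n_lg = nrow(per),
         total_cM = sum(per$len),
         mean_spacing_cM = sum(per$len) / max(nrow(x) - nrow(per), 1),
         map_function = attr(x, "map_function") %||% NA_character_)
}

#' @method tidy cucumap_consensus
#' @export
tidy.cucumap_consensus <- function(x, ...) {
  as_tibble(x)[, c("lg", "marker", "cM", "is_skeleton", "source_map")]
}

#' @method glance cucumap_consensus
#' @export
glance.cucumap_consensus <- function(x, ...) {
  per <- as_tibble(x) |>
    group_by(.data$lg) |>
    summarise(len = max(.data$cM), .groups = "drop")
  tibble(n_loci = nrow(x), n_lg = nrow(per),
         n_skeleton = sum(x$is_skeleton),
         total_cM = sum(per$len),
         mean_spacing_cM = sum(per$len) / max(nrow(x) - nrow(per), 1))
}

#' @method tidy cucumap_tree
#' @export
tidy.cucumap_tree <- function(x, ...) {
  n_tip <- length(x$tip.label)
  edges <- tibble(parent = x$edge[, 1], node = x$edge[, 2],
                  length = x$edge.length)
  tip <- edges$node <= n_tip
  edges$label <- NA_character_
  edges$label[tip] <- x$tip.label[edges$node[tip]]
  edges$support <- NA_real_
  if (!is.null(x$node.label)) {
    edges$support[!tip] <- as.numeric(x$node.label[edges$node[!tip] - n_tip])
  }
  edges
}

#' @method glance cucumap_tree
#' @export
glance.cucumap_tree <- function(x, ...) {
  tibble(n_leaves = length(x$tip.label),
         n_bootstrap = attr(x, "n_bootstrap") %||% 0,
         min_support = if (is.null(x$node.label)) NA_real_ else
           suppressWarnings(min(as.numeric(x$node.label), na.rm = TRUE)))
}

#' @method glance cucumap_anchors
#' @export
glance.cucumap_anchors <- function(x, ...) {
  attr(x, "totals")
}

#' Plot a genetic map
#'
#' Rug of marker positions per linkage group; consensus maps distinguish
#' skeleton from refilled loci.
#'
#' @param object A `cucumap_map` or `cucumap_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cucumap_map
#' @export
autoplot.cucumap_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lg, y = .data$cM)) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)",
                  title = attr(object, "map_name")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cucumap_map
#' @method autoplot cucumap_consensus
#' @export
autoplot.cucumap_consensus <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lg, y = .data$cM,
                               colour = .data$is_skeleton)) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)",
                  colour = "skeleton") +
    ggplot2::theme_minimal()
}

#' Plot genetic-versus-physical marker positions
#'
#' @param consensus Map tibble `marker`, `lg`, `cM`.
#' @param positions Tibble `marker`, `scaffold_id`, `start_bp`.
#' @return A ggplot object.
#' @export
plot_colinearity <- function(consensus, positions) {
  d <- left_join(as_tibble(consensus), positions, by = "marker") |>
    filter(!is.na(.data$start_bp))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cM, y = .data$start_bp,
                                  colour = .data$scaffold_id)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::facet_wrap(~lg, scales = "free") +
    ggplot2::labs(x = "genetic position (cM)", y = "physical position (bp)") +
    ggplot2::theme_minimal()
}
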