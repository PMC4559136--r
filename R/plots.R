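#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a taxon dissimilarity matrix
#'
#' @param object A `glyco_dissimilarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_dissimilarity <- function(object, ...) {
  m <- as.matrix(unclass(object))
  df <- tibble::as_tibble(as.table(m), .name_repair = ~ c("taxon1", "taxon2",
                                                          "distance"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon1, y = .data$taxon2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(m))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of a fragment abundance table
#'
#' @param object An `abundance_table`.
#' @param top Number of most abundant fragments to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_table <- function(object, top = 20, ...) {
  df <- utils::head(tidy(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$fragment,
                                                      .data$absolute),
                                   y = .data$absolute)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "absolute abundance") +
    ggplot2::theme_minimal()
}

# segment coordinates of an hclust dendrogram, tips at height 0
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- stats::setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  segs <- list()
  node_pos <- function(k) {
    if (k < 0) c(x = unname(xpos[as.character(-k)]), h = 0)
    else c(x = node_x[k], h = hc$height[k])
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- node_pos(hc$merge[k, 1])
    b <- node_pos(hc$merge[k, 2])
    h <- hc$height[k]
    node_x[k] <- mean(c(a["x"], b["x"]))
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]), xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], b["h"], h), yend = c(h, h, h))
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram or heatmap of a clustering result
#'
#' Hierarchical results are drawn as a rectangular dendrogram; for
#' neighbor-joining and minimum-evolution results (unrooted trees) the
#' dissimilarity heatmap is shown instead, and [ape::plot.phylo()] on
#' `object$tree` is the tool of choice for the tree itself.
#'
#' @param object A `glyco_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_clustering <- function(object, ...) {
  hc <- attr(object$tree, "hclust")
  if (is.null(hc)) return(autoplot(object$matrix))
  segs <- dendrogram_segments(hc)
  tips <- tibble::tibble(x = seq_along(hc$order),
                         label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult =
                                                              c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot a coverage table
#'
#' @param x A `coverage_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coverage <- function(x, ...) {
  df <- dplyr::filter(x, .data$subtaxon != "(cumulative)")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$subtaxon,
                                                      .data$n_structures),
                                   y = .data$n_structures,
                                   fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "structures", fill = NULL) +
    ggplot2::theme_minimal()
}
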