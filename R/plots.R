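# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_col geom_text labs theme_minimal scale_fill_viridis_c coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates with axis percentages in
#' the labels, mirroring the usual presentation of site ordinations on a
#' PhiPT matrix.
#'
#' @param object a `pcoa_ord`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pcoa_ord <- function(object, ...) {
  df <- tidy(object)
  if (!all(c("Axis1", "Axis2") %in% names(df))) {
    abort("need at least two positive axes to plot")
  }
  pct <- object$percent
  ggplot(df, aes(x = .data$Axis1, y = .data$Axis2)) +
    geom_point(size = 2) +
    geom_text(aes(label = .data$object), vjust = -0.8, size = 3) +
    labs(x = sprintf("Axis 1 (%.1f%%)", pct[1]),
         y = sprintf("Axis 2 (%.1f%%)", pct[2])) +
    theme_minimal()
}

#' Plot a pairwise PhiPT matrix
#'
#' @param object a `phi_pt` result with pairwise values.
#' @param ... unused.
#' @return a ggplot heatmap of clamped pairwise PhiPT.
#' @export
autoplot.phi_pt <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$site1, y = .data$site2, fill = .data$phi)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = "PhiPT") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a median-joining haplotype network
#'
#' Nodes are placed by classical multidimensional scaling of the shortest
#' network path lengths; observed haplotypes are sized by frequency, median
#' vectors drawn as small grey points, and edges annotated with their
#' mutational steps.
#'
#' @param object a `haplo_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.haplo_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  n <- nrow(nodes)
  idx <- setNames(seq_len(n), nodes$node)
  # shortest-path matrix over edge steps (Floyd-Warshall; networks are small)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- idx[edges$from[r]]; j <- idx[edges$to[r]]
    D[i, j] <- D[j, i] <- min(D[i, j], edges$steps[r])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    relax <- D[i, k] + D[k, ]
    better <- relax < D[i, ]
    D[i, better] <- relax[better]
  }
  D[!is.finite(D)] <- max(D[is.finite(D)]) * 1.5
  xy <- stats::cmdscale(D, k = 2)
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  edges$x <- nodes$x[idx[edges$from]]; edges$y <- nodes$y[idx[edges$from]]
  edges$xend <- nodes$x[idx[edges$to]]; edges$yend <- nodes$y[idx[edges$to]]
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey60") +
    geom_point(data = dplyr::filter(nodes, .data$type == "median"),
               aes(x = .data$x, y = .data$y), shape = 21, size = 2,
               fill = "grey70") +
    geom_point(data = dplyr::filter(nodes, .data$type == "observed"),
               aes(x = .data$x, y = .data$y,
                   size = pmax(.data$frequency, 1)),
               shape = 21, fill = "steelblue", alpha = 0.8) +
    geom_text(data = dplyr::filter(nodes, .data$type == "observed"),
              aes(x = .data$x, y = .data$y, label = .data$node),
              vjust = -1, size = 3) +
    ggplot2::scale_size_area(name = "colonies", max_size = 10) +
    coord_equal() +
    ggplot2::theme_void()
}

#' Bar chart of per-site unbiased haplotype diversity
#'
#' @param diversity a [diversity_summary()] tibble.
#' @return a ggplot.
#' @export
plot_site_diversity <- function(diversity) {
  ggplot(diversity,
         aes(x = stats::reorder(.data$site, .data$uh), y = .data$uh)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "unbiased haplotype diversity (uh)") +
    theme_minimal() +
    ggplot2::coord_flip()
}
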