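#' Biplot of a trait PCA
#'
#' Genotype scores as points and trait loading arrows (scaled by the
#' square root of the eigenvalue) on two components.
#'
#' @param object A [trait_pca()] result.
#' @param components Integer pair of components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trait_pca <- function(object, components = c(1, 2), ...) {
  bc <- biplot_coordinates(object, components)
  lam <- object$eigenvalues
  labs <- sprintf("PC%d (%.1f%%)", components,
                  lam$proportion[components])
  arrow_scale <- max(abs(c(bc$genotypes$x, bc$genotypes$y))) /
    max(abs(c(bc$traits$x, bc$traits$y, 1e-9)))
  tr <- dplyr::mutate(bc$traits, x = .data$x * arrow_scale,
                      y = .data$y * arrow_scale)
  ggplot2::ggplot(bc$genotypes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, colour = "grey30") +
    ggplot2::geom_segment(data = tr,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = ggplot2::arrow(length = grid::unit(2, "mm")),
                          colour = "steelblue") +
    ggplot2::geom_text(data = tr,
                       ggplot2::aes(label = .data$trait),
                       colour = "steelblue", vjust = -0.4, size = 3) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param object A [trait_correlations()] result.
#' @param ... Unused.
#' @return A ggplot tile map of Pearson r with significance stars.
#' @exportS3Method ggplot2::autoplot
autoplot.trait_correlations <- function(object, ...) {
  df <- tidy(object)
  both <- dplyr::bind_rows(df,
                           dplyr::rename(df, trait1 = "trait2",
                                         trait2 = "trait1"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$trait1, y = .data$trait2,
                                     fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Genotype ranking plot for MGIDI
#'
#' Genotypes in ascending index order (best first); the selected fraction
#' highlighted, with the cut point marked.
#'
#' @param object An [mgidi()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mgidi_result <- function(object, ...) {
  df <- object$index
  df$genotype <- factor(df$genotype, levels = rev(df$genotype))
  cut_at <- length(object$selected) + 0.5
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mgidi, y = .data$genotype,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = nrow(df) - cut_at + 1,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = "selected") +
    ggplot2::labs(x = "MGIDI (lower = closer to ideotype)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Dendrogram of a genotype clustering
#'
#' @param object A [cluster_genotypes()] result.
#' @param ... Unused.
#' @return A ggplot dendrogram (segments drawn from the merge tree).
#' @exportS3Method ggplot2::autoplot
autoplot.genotype_clusters <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # collect segment coordinates by walking the dendrogram
  segs <- dendrogram_segments(dend)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$labels[hc$order]),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

# flatten a dendrogram into a tibble of line segments
dendrogram_segments <- function(d) {
  leaf_x <- new.env()
  assign("next_x", 1, envir = leaf_x)
  walk <- function(node) {
    if (is.leaf(node)) {
      x <- get("next_x", envir = leaf_x)
      assign("next_x", x + 1, envir = leaf_x)
      return(list(x = x, h = 0, segs = NULL))
    }
    l <- walk(node[[1]]); r <- walk(node[[2]])
    h <- attr(node, "height")
    segs <- dplyr::bind_rows(
      l$segs, r$segs,
      tibble(x = c(l$x, r$x, l$x), y = c(l$h, r$h, h),
             xend = c(l$x, r$x, r$x), yend = c(h, h, h)))
    list(x = (l$x + r$x) / 2, h = h, segs = segs)
  }
  walk(d)$segs
}

#' Diversity index bar chart
#'
#' @param object A [diversity_profile()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of normalised Shannon-Weaver indices.
#' @exportS3Method ggplot2::autoplot
autoplot.diversity_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$descriptor <- factor(df$descriptor,
                          levels = df$descriptor[order(df$h_norm)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h_norm,
                                   y = .data$descriptor)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "normalised Shannon-Weaver index", y = NULL) +
    ggplot2::theme_minimal()
}
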