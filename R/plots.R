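#' Plot a persistence histogram
#'
#' Bar chart of the cluster-persistence distribution; bacterial samples
#' typically show the characteristic U shape with mass near 1/n (rare,
#' often horizontally acquired clusters) and at 1 (the core).
#'
#' @param persistence Output of [cluster_persistence()] or a numeric
#'   vector of persistence values.
#' @param bins Number of equal bins on (0, 1].
#' @return A ggplot object.
#' @export
plot_persistence <- function(persistence, bins = 20) {
  h <- persistence_histogram(persistence, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$lower + .data$upper) / 2, y = .data$count)) +
    ggplot2::geom_col(width = 1 / bins, fill = "grey35") +
    ggplot2::labs(
      x = "cluster persistence",
      y = "number of clusters"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.heaps_fit <- function(object, ...) {
  if (object$openness == "degenerate") {
    abort("cannot plot a degenerate Heaps fit")
  }
  means <- object$data |>
    dplyr::group_by(.data$j) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  curve <- tibble::tibble(
    j = seq(min(object$data$j), max(object$data$j), length.out = 200)
  )
  curve$y <- object$kappa * curve$j^(-object$alpha)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$j, y = .data$y)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "genomes added (j)",
      y = "new clusters",
      title = sprintf(
        "Heaps' law fit: alpha = %.3g (%s pan-genome)",
        object$alpha, object$openness
      )
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.presence_pca <- function(object, ...) {
  scores <- object$scores
  if (ncol(scores) < 3) {
    abort("need at least two components to plot")
  }
  xlab <- sprintf("PC1 (%.1f%%)", 100 * object$explained[1])
  ylab <- sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_comparison <- function(object, ...) {
  bins <- c("one-to-one", as.character(1:5), "6+")
  df <- tidy(object) |>
    dplyr::mutate(bin = factor(.data$bin, levels = bins))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(
      x = "counterpart clusters (N)",
      y = "reference clusters"
    ) +
    ggplot2::theme_minimal()
}
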