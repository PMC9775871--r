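#' Plot a lexical network
#'
#' Force-directed (Fruchterman-Reingold) layout with edges shaded by weight;
#' when a `community_partition` is supplied, nodes are coloured by community
#' — the standard way of eyeballing the cluster structure of a fluency
#' network.
#'
#' @param object A `lexical_network`.
#' @param communities Optional `community_partition` from
#'   [detect_communities()].
#' @param seed Seed for the layout.
#' @param label_nodes Draw word labels (default TRUE for <= 60 nodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lexical_network
#' @export
autoplot.lexical_network <- function(object, communities = NULL, seed = 1L,
                                     label_nodes = NULL, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(word = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L])
  if (!is.null(communities)) {
    nodes <- dplyr::left_join(nodes, tidy(communities), by = "word")
    nodes$community <- factor(nodes$community)
  }
  edges <- tidy(object)
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[c("word", "x", "y")],
                                          xa = "x", ya = "y"),
                            by = c(word_a = "word"))
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[c("word", "x", "y")],
                                          xb = "x", yb = "y"),
                            by = c(word_b = "word"))
  label_nodes <- label_nodes %||% (nrow(nodes) <= 60L)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   alpha = abs(.data$weight)),
      colour = "grey40", show.legend = FALSE) +
    ggplot2::theme_void()
  p <- if (is.null(communities)) {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y), size = 3)
  } else {
    p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$community), size = 3) +
      ggplot2::labs(colour = "community")
  }
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$word),
      vjust = -0.8, size = 2.6)
  }
  p
}

#' Plot a null ensemble
#'
#' Histograms of the per-replicate clustering coefficient, average shortest
#' path length and modularity of the Erdos-Renyi ensemble, with optional
#' vertical lines marking the empirical values being compared to the null.
#'
#' @param object A `null_ensemble`.
#' @param empirical Optional named vector of empirical values, e.g.
#'   `c(cc = 0.97, aspl = 1.03, q = 0.72)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_ensemble
#' @export
autoplot.null_ensemble <- function(object, empirical = NULL, ...) {
  long <- tidyr::pivot_longer(object$samples, c("cc", "aspl", "q"),
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "replicates",
      title = sprintf("Erdos-Renyi null ensemble: G(%d, %.2f), %d replicates",
                      object$n, object$p, object$reps)) +
    ggplot2::theme_minimal()
  if (!is.null(empirical)) {
    emp <- tibble::tibble(metric = names(empirical), value = unname(empirical))
    p <- p + ggplot2::geom_vline(data = emp,
                                 ggplot2::aes(xintercept = .data$value),
                                 colour = "firebrick", linewidth = 0.8)
  }
  p
}

#' Plot per-condition priming means
#'
#' Dot-and-error plot of mean RT by stimulus type within each language
#' condition; the gap between unlearned and learned dots is the priming
#' effect.
#'
#' @param trials A (preprocessed) trial tibble.
#' @return A ggplot object.
#' @export
plot_priming_means <- function(trials) {
  trials <- validate_trials(trials)
  cell <- trials |>
    dplyr::group_by(.data$language_condition, .data$stimulus_type) |>
    dplyr::summarise(mean = mean(.data$rt_ms),
                     se = stats::sd(.data$rt_ms) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$language_condition,
                                     y = .data$mean,
                                     colour = .data$stimulus_type)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "language condition", y = "mean RT (ms)",
                  colour = "stimulus type") +
    ggplot2::theme_minimal()
}
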