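#' Volcano plot of differential genera
#'
#' log2 abundance ratio against -log10 p, significant genera (BH-adjusted)
#' highlighted and labelled.
#'
#' @param object A `genus_diff` result from [two_group_t_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genus_diff
#' @export
autoplot.genus_diff <- function(object, ...) {
  dat <- object %>%
    as_tibble() %>%
    filter(.data$tested) %>%
    mutate(minus_log10_p = -log10(pmax(.data$p_value, 1e-300)))
  groups <- attr(object, "groups")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_ratio,
                                    y = .data$minus_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_text(data = filter(dat, .data$significant),
                       ggplot2::aes(label = .data$genus),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("log2 ratio (%s / %s)", groups[1L], groups[2L]),
      y = "-log10 p", colour = "BH significant",
      title = "Differentially abundant genera") +
    ggplot2::theme_minimal()
}

# Segment coordinates of an hclust dendrogram (leaves at heights 0,
# x positions following tree$order).
dendrogram_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- match(seq_len(n), tree$order)
  centers <- numeric(nrow(tree$merge))
  segs <- vector("list", nrow(tree$merge))
  coord <- function(m) {
    if (m < 0) c(x = leaf_x[-m], y = 0) else
      c(x = centers[m], y = tree$height[m])
  }
  for (k in seq_len(nrow(tree$merge))) {
    a <- coord(tree$merge[k, 1L])
    b <- coord(tree$merge[k, 2L])
    h <- tree$height[k]
    centers[k] <- (a["x"] + b["x"]) / 2
    segs[[k]] <- tibble(
      x = c(a["x"], b["x"], a["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["y"], b["y"], h),
      yend = c(h, h, h)
    )
  }
  list_rbind(segs)
}

#' Dendrogram of a sample clustering
#'
#' @param object A `calc_hclust` from [hierarchical_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calc_hclust
#' @export
autoplot.calc_hclust <- function(object, ...) {
  tree <- object$tree
  segs <- dendrogram_segments(tree)
  leaves <- tibble(
    x = seq_along(tree$order),
    label = tree$labels[tree$order],
    group = factor(object$groups[tree$labels[tree$order]])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label,
                                    colour = .data$group),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(y = "Pearson correlation distance", x = NULL,
                  colour = "flat group",
                  title = "Hierarchical clustering of samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Stacked genus distribution bar chart
#'
#' Fractional genus abundances per sample for the top-N genera (ordered by
#' mean abundance), the classic community composition figure.
#'
#' @param object A `genus_fractions` tibble.
#' @param top_n Number of genera shown individually (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genus_fractions
#' @export
autoplot.genus_fractions <- function(object, top_n = 20L, ...) {
  dat <- top_genera(object, top_n)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$raw_file, y = .data$fraction,
                                    fill = .data$genus)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of bacterial LFQ intensity",
                  fill = "genus",
                  title = "Genus-level community composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname autoplot.genus_fractions
#' @param fractions A `genus_fractions` tibble.
#' @export
plot_genus_bars <- function(fractions, top_n = 20L) {
  autoplot.genus_fractions(fractions, top_n = top_n)
}
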