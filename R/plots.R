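# ggplot2 views of the main result types. These return plot objects;
# styling is left to the caller.

#' Volcano plot of a differential comparison
#'
#' @param volcano table from [volcano_prep()].
#' @param label_top label the n most significant lipids (0 = none).
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, label_top = 0) {
  p <- ggplot2::ggplot(volcano, ggplot2::aes(
    x = .data$log2_fc, y = .data$neg_log10_p, colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(
        c("#c0392b", "#2980b9", "grey70"),
        c(
          setdiff(unique(volcano$direction), "ns"),
          "ns"
        )[c(1, 2, 3)]
      ),
      na.value = "grey70"
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 p", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    top <- volcano[order(volcano$p_value), ][seq_len(label_top), ]
    p <- p + ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data$lipid),
      size = 2.5, vjust = -0.6, show.legend = FALSE
    )
  }
  p
}

#' Banded class-distribution plot of a lipidome
#'
#' Log-scale species concentrations per subclass with the subclass total
#' as a bold tick.
#'
#' @param dist_data table from [distribution_plot_data()].
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(dist_data) {
  dist_data$subclass <- stats::reorder(
    dist_data$subclass, -dist_data$class_total_pmol_mg
  )
  ggplot2::ggplot(dist_data, ggplot2::aes(
    x = .data$subclass, y = .data$mean_pmol_mg
  )) +
    ggplot2::geom_point(
      shape = 95, size = 4, alpha = 0.6, colour = "steelblue"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$class_total_pmol_mg),
      shape = 95, size = 8, colour = "black"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "concentration (pmol/mg, log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scatter view of the lipidome UMAP embedding
#'
#' @param embedding tibble from [embed_lipidome()].
#' @param colour_by column to colour points by (default subclass).
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, colour_by = "subclass") {
  ggplot2::ggplot(embedding, ggplot2::aes(
    x = .data$umap_1, y = .data$umap_2,
    colour = if (colour_by %in% names(embedding)) {
      .data[[colour_by]]
    } else {
      NULL
    }
  )) +
    ggplot2::geom_point(size = 1.4, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Two-stage band plot of a sphingolipid flow
#'
#' A segment rendering of the Sankey links: sphingoid bases to
#' subclasses, subclasses to N-acyls, segment width proportional to the
#' link share.
#'
#' @param flow an `av_sphingo_flow` object from [sphingo_flow()].
#' @return A ggplot object.
#' @export
plot_sphingo_flow <- function(flow) {
  links <- tibble::as_tibble(flow)
  links$x <- ifelse(links$side == "base_to_subclass", 1, 2)
  links$xend <- links$x + 1
  pos_of <- function(keys) {
    u <- unique(keys)
    stats::setNames(seq_along(u), u)
  }
  lp <- pos_of(links$source[links$side == "base_to_subclass"])
  mp <- pos_of(links$source[links$side == "subclass_to_acyl"])
  rp <- pos_of(links$target[links$side == "subclass_to_acyl"])
  links$y <- ifelse(
    links$side == "base_to_subclass", lp[links$source], mp[links$source]
  )
  links$yend <- ifelse(
    links$side == "base_to_subclass", mp[links$target], rp[links$target]
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(x = 1, y = unname(lp), label = names(lp)),
    tibble::tibble(x = 2, y = unname(mp), label = names(mp)),
    tibble::tibble(x = 3, y = unname(rp), label = names(rp))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(
        x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
        linewidth = .data$percent
      ),
      alpha = 0.5, colour = "steelblue"
    ) +
    ggplot2::geom_label(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 2.8
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 6)) +
    ggplot2::labs(x = NULL, y = NULL, linewidth = "% of pool") +
    ggplot2::theme_void()
}
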