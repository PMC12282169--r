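# ggplot2 views of the main result types.

#' @describeIn design_matrix Heatmap of probe counts over the (top_n, gap)
#'   grid.
#' @param object A `design_matrix`.
#' @param ... Unused.
#' @export
autoplot.design_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$gap), y = factor(.data$top_n), fill = .data$n_probes
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_probes), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "probes") +
    ggplot2::labs(
      x = "gap between adjacent probes (nt)",
      y = "top abundant regions per sample",
      title = "Probe counts across the design grid"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn design_probe_set Probe layout along each targeted reference.
#' @param object A `probe_set`.
#' @export
autoplot.probe_set <- function(object, ...) {
  probes <- object$probes
  ggplot2::ggplot(probes) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$target_start, xend = .data$target_end,
        y = .data$ref_id, yend = .data$ref_id
      ),
      linewidth = 3, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "reference position (bp)", y = NULL,
      title = sprintf(
        "%d antisense probes (%d nt, gap %d nt)",
        nrow(probes), object$config$probe_length, object$config$gap
      )
    ) +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of per-sample read partitions
#'
#' @param reports Partition report tibble (`sample_id`, `category`,
#'   `fraction`), e.g. `bind_rows()` over [partition_report()] outputs.
#' @return A ggplot object.
#' @export
plot_partition <- function(reports) {
  ggplot2::ggplot(reports, ggplot2::aes(
    x = .data$sample_id, y = .data$fraction, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      rRNA = "#d95f02", host = "#7570b3", retained = "#1b9e77"
    )) +
    ggplot2::labs(x = NULL, y = "fraction of reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coverage track with extracted regions
#'
#' @param coverage Coverage tibble from [compute_coverage()].
#' @param regions Optional region tibble to overlay.
#' @param ref_id Reference to plot (default: first in `coverage`).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, regions = NULL, ref_id = coverage$ref_id[1]) {
  depth <- coverage$depth[[match(ref_id, coverage$ref_id)]]
  df <- tibble(pos = seq_along(depth) - 1L, depth = depth)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(
      x = "reference position (bp)", y = "coverage depth (reads)", title = ref_id
    ) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    r <- regions[regions$ref_id == ref_id, , drop = FALSE]
    if (nrow(r)) {
      p <- p + ggplot2::annotate(
        "rect", xmin = r$start, xmax = r$end, ymin = 0, ymax = max(df$depth),
        alpha = 0.15, fill = "steelblue"
      )
    }
  }
  p
}
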