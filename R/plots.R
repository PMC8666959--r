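#' Lick raster with tone epochs
#'
#' Plots lick timestamps as a raster (one row per rat-session) over the
#' session timeline, with tone epochs shaded.
#'
#' @param licks A lick table (`rat_id`, `session_id`, `timestamp_s`).
#' @param design Optional [fc_design()]; when given, tone epochs are shaded.
#' @return A ggplot object.
#' @export
plot_lick_raster <- function(licks, design = NULL) {
  licks <- tibble::as_tibble(licks)
  licks$train <- if (all(c("rat_id", "session_id") %in% names(licks))) {
    paste(licks$rat_id, licks$session_id)
  } else {
    "train"
  }
  p <- ggplot2::ggplot(licks)
  if (!is.null(design)) {
    tones <- dplyr::filter(epoch_partition(design), .data$phase == "tone")
    p <- p + ggplot2::geom_rect(
      data = tones,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85", inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$timestamp_s, y = .data$train),
      shape = "|", size = 3
    ) +
    ggplot2::labs(x = "Session time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn classify_phenotype Plot per-session tertile trajectories
#'   colored by final phenotype label.
#' @param object A `phenotype_tbl`.
#' @param ... Unused.
#' @export
autoplot.phenotype_tbl <- function(object, ...) {
  tert <- attr(object, "tertiles")
  if (is.null(tert)) {
    bt_abort("No tertile table attached to this phenotype result.", "bad_argument")
  }
  df <- dplyr::left_join(tert,
                         tidy(object)[, c("rat_id", "label")],
                         by = "rat_id")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$session_id, y = .data$intake,
    group = .data$rat_id, colour = .data$label
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Stress session", y = "Sucrose intake (g)",
                  colour = "Phenotype") +
    ggplot2::theme_minimal()
}

#' Group mean +/- SD bar plot
#'
#' Plots a [region_group_summary()]-style table (or any tibble with `n`,
#' mean and SD columns) as bars with SD error bars, faceted by region when
#' present.
#'
#' @param summary_tbl A tibble with a grouping column, `mean_od` and
#'   `sd_od` (or `mean`/`sd`).
#' @param group_col Name of the x-axis grouping column.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary_tbl, group_col) {
  mcol <- if ("mean_od" %in% names(summary_tbl)) "mean_od" else "mean"
  scol <- if ("sd_od" %in% names(summary_tbl)) "sd_od" else "sd"
  p <- ggplot2::ggplot(summary_tbl, ggplot2::aes(
    x = .data[[group_col]], y = .data[[mcol]]
  )) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]]
    ), width = 0.2) +
    ggplot2::labs(y = "Mean ± SD") +
    ggplot2::theme_minimal()
  if ("region" %in% names(summary_tbl)) {
    p <- p + ggplot2::facet_wrap(~region, scales = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
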