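# Plotting. All plots are ggplot2 objects the caller can restyle.

#' Microhomology distribution: observed vs control
#'
#' Bar chart of the fraction of junctions per microhomology length,
#' observed breakpoints against the random control population. Control
#' microhomology clusters at 0-1 bp while observed junctions carry longer
#' stretches.
#'
#' @param mh_observed,mh_control Integer microhomology lengths.
#' @param max_bin Lengths at or above this are pooled into one bin.
#' @return A ggplot object.
#' @export
plot_mh_distribution <- function(mh_observed, mh_control, max_bin = 10L) {
  bin <- function(x) {
    f <- pmin(x, max_bin)
    factor(ifelse(f >= max_bin, paste0(">=", max_bin), f),
           levels = c(0:(max_bin - 1L), paste0(">=", max_bin)))
  }
  df <- dplyr::bind_rows(
    tibble(population = "observed", mh = bin(mh_observed)),
    tibble(population = "control", mh = bin(mh_control))) |>
    dplyr::count(.data$population, .data$mh, .drop = FALSE) |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mh, y = .data$fraction,
                                   fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "microhomology (bp)", y = "fraction of junctions",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Microhomology histogram for an enrichment report
#'
#' @param object A `junction_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot junction_enrichment
#' @export
autoplot.junction_enrichment <- function(object, ...) {
  plot_mh_distribution(object$mh$observed, object$mh$control)
}

#' Architecture sketch of one breakpoint region
#'
#' Draws motif hits and non-B features along a region with the breakpoint
#' marked, in the style of per-deletion breakpoint-region schematics.
#'
#' @param region One-row region tibble (`id`, `seq`, `breakpoint_offset`).
#' @param profile The matching row of [scan_regions()] output.
#' @return A ggplot object.
#' @export
plot_region_architecture <- function(region, profile) {
  hits <- profile$motif_hits[[1]]
  feats <- profile$nonb_features[[1]]
  segs <- dplyr::bind_rows(
    if (nrow(hits)) dplyr::transmute(hits, start = .data$start,
                                     end = .data$end, track = "motifs",
                                     label = .data$motif_id),
    if (nrow(feats)) dplyr::transmute(feats, start = .data$arm1_start,
                                      end = dplyr::coalesce(.data$arm2_end,
                                                            .data$arm1_end),
                                      track = "non-B", label = .data$kind))
  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = region$breakpoint_offset[[1]],
                        linetype = "dashed", colour = "red") +
    ggplot2::xlim(0, nchar(region$seq[[1]])) +
    ggplot2::labs(title = region$id[[1]], x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(segs) && nrow(segs)) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$track,
                   yend = .data$track, colour = .data$label),
      linewidth = 3)
  }
  p
}
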