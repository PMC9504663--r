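#' Side-by-side alignment plot of genetic, physical and pseudochromosome maps
#'
#' Mirrors the conventional three-column map-alignment figure: each map is a
#' vertical bar (position normalised to 0–100 within the map, top = short
#' arm end), markers are labelled points, and line segments connect the same
#' marker across adjacent maps, so order inversions show as crossing lines.
#'
#' @param entries Entry tibble as consumed by [build_report()] (columns
#'   `marker_id` and at least two of `genetic_cM`, `physical_fl`,
#'   `pseudo_mbp`).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_map_alignment <- function(entries, title = NULL) {
  coords <- c(genetic = "genetic_cM", physical = "physical_fl",
              pseudo = "pseudo_mbp")
  coords <- coords[coords %in% names(entries)]
  long <- purrr::imap(coords, function(col, map) {
    v <- entries[[col]]
    keep <- !is.na(v)
    rng <- range(v[keep])
    tibble(map = map, marker_id = entries$marker_id[keep],
           pos = if (diff(rng) > 0) {
             100 * (v[keep] - rng[1]) / diff(rng)
           } else rep(50, sum(keep)))
  }) |> purrr::list_rbind() |>
    mutate(map = factor(.data$map, levels = names(coords)))
  segs <- long |>
    mutate(map_i = as.integer(.data$map)) |>
    tidyr::pivot_wider(id_cols = "marker_id", names_from = "map_i",
                       values_from = "pos", names_prefix = "m")
  seg_layers <- list()
  for (i in seq_len(length(coords) - 1)) {
    a <- paste0("m", i); b <- paste0("m", i + 1)
    if (all(c(a, b) %in% names(segs))) {
      seg_layers[[i]] <- ggplot2::geom_segment(
        data = filter(segs, !is.na(.data[[a]]), !is.na(.data[[b]])),
        ggplot2::aes(x = i, xend = i + 1, y = .data[[a]],
                     yend = .data[[b]]),
        colour = "grey55", linewidth = 0.3)
    }
  }
  ggplot2::ggplot(long, ggplot2::aes(x = as.integer(.data$map),
                                     y = .data$pos)) +
    seg_layers +
    ggplot2::geom_point(size = 1.8, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$marker_id),
                       hjust = -0.15, size = 2.6, check_overlap = TRUE) +
    ggplot2::scale_x_continuous(breaks = seq_along(coords),
                                labels = names(coords),
                                limits = c(0.5, length(coords) + 0.7)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "relative position (top = short arm)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @describeIn build_report Map-alignment plot of the report's entries.
#' @param object A `tyr_concordance` object.
#' @export
autoplot.tyr_concordance <- function(object, ...) {
  plot_map_alignment(object$entries)
}

#' Idiogram-style plot of probe positions on a chromosome
#'
#' Draws the chromosome as a vertical bar (short arm up), the centromere at
#' FL = 100 * f_s, and each probe at its FL position.
#'
#' @param positions Positions tibble (`probe_id`, `rphc_mean`, `arm`).
#' @param short_arm_fraction Short-arm fraction of the chromosome.
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_positions <- function(positions, short_arm_fraction, title = NULL) {
  ord <- physical_order(positions, short_arm_fraction)
  cen <- 100 * short_arm_fraction
  ggplot2::ggplot(ord, ggplot2::aes(y = .data$fl)) +
    ggplot2::annotate("rect", xmin = -0.12, xmax = 0.12, ymin = 0,
                      ymax = 100, fill = "grey85", colour = "grey30") +
    ggplot2::annotate("point", x = 0, y = cen, shape = 21, size = 4,
                      fill = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = 0), size = 2,
                        colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(x = 0.16, label = .data$probe_id),
                       hjust = 0, size = 2.8) +
    ggplot2::scale_y_reverse(limits = c(100, 0)) +
    ggplot2::scale_x_continuous(limits = c(-0.3, 1.2), breaks = NULL) +
    ggplot2::labs(x = NULL, y = "FL (%)", title = title) +
    ggplot2::theme_minimal()
}
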