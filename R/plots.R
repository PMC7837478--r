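#' Plot a line profile
#'
#' @param object A `line_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot line_profile
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$distance_um, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from terminus (µm)",
                  y = if (isTRUE(attr(object, "normalized")))
                    "Normalized intensity" else "Intensity") +
    ggplot2::theme_minimal()
}

#' Plot a motif as a per-position probability profile
#'
#' @param object A [motif].
#' @param ... Unused.
#' @return A ggplot (stacked per-position base probabilities).
#' @method autoplot motif
#' @export
autoplot.motif <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$position, .data$probability,
                               fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(title = sprintf("%s (%s)", object$name, consensus(object)),
                  x = "Position", y = "Probability") +
    ggplot2::theme_minimal()
}

#' Plot a two-group profile comparison
#'
#' Mean normalized intensity by distance with 95 percent confidence ribbons
#' for both groups.
#'
#' @param comparison Output of [profile_group_compare()].
#' @param labels Length-2 group labels.
#' @return A ggplot.
#' @export
plot_profile_comparison <- function(comparison, labels = c("A", "B")) {
  long <- bind_rows(
    tibble(distance_um = comparison$distance_um, group = labels[1],
           mean = comparison$mean_a, lo = comparison$ci_lo_a,
           hi = comparison$ci_hi_a),
    tibble(distance_um = comparison$distance_um, group = labels[2],
           mean = comparison$mean_b, lo = comparison$ci_lo_b,
           hi = comparison$ci_hi_b))
  ggplot2::ggplot(long, ggplot2::aes(.data$distance_um, .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from terminus (µm)",
                  y = "Normalized intensity", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of motif occurrences per transcript region
#'
#' @param summary Summary tibble from [classify_positions()] (columns
#'   `region`, `percent`).
#' @return A ggplot.
#' @export
plot_position_summary <- function(summary) {
  lev <- intersect(c("utr5", "cds", "utr3", "other"), summary$region)
  ggplot2::ggplot(mutate(summary, region = factor(.data$region, lev)),
                  ggplot2::aes(.data$region, .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of occurrences") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
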