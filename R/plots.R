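#' Plot a phaseogram
#'
#' Genome-averaged dyad-distance frequency curve; the oscillation period is
#' the nucleosome repeat length.
#'
#' @param object A `phaseogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phaseogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$distance, y = .data$frequency)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "dyad-dyad distance (bp)", y = "frequency",
                  title = "Dyad-distance phaseogram") +
    ggplot2::theme_minimal()
}

#' Plot an NRL fit
#'
#' Detected peak positions against peak order with the fitted regression
#' line; the slope is the NRL.
#'
#' @param object An `nrl_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nrl_estimate <- function(object, ...) {
  ggplot2::ggplot(object$peaks,
                  ggplot2::aes(x = .data$k, y = .data$position)) +
    ggplot2::geom_abline(slope = object$nrl, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "peak order k", y = "peak position (bp)",
                  title = sprintf("NRL = %.1f bp (R² = %.3f)",
                                  object$nrl, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot an aggregate occupancy profile
#'
#' @param object An `occupancy_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.occupancy_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30", na.rm = TRUE) +
    ggplot2::labs(x = "distance from feature centre (bp)", y = "occupancy",
                  title = "Aggregate occupancy profile") +
    ggplot2::theme_minimal()
}

#' Plot an aggregate methylation profile
#'
#' @param object A `methylation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.methylation_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$offset, y = .data$beta_sum)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "distance from feature centre (bp)",
                  y = "DNA methylation (a.u.)",
                  title = "Aggregate methylation profile") +
    ggplot2::theme_minimal()
}

#' Plot a fragment-length histogram
#'
#' Length distribution of MNase-protected fragments, with the canonical
#' fractionation bin edges marked.
#'
#' @param fragments Fragment tibble.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_fragment_lengths <- function(fragments, binwidth = 2) {
  edges <- unique(c(fragment_size_bins()$low, fragment_size_bins()$high))
  ggplot2::ggplot(fragments, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = edges, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::labs(x = "fragment length (bp)", y = "count",
                  title = "Protected fragment sizes") +
    ggplot2::theme_minimal()
}
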