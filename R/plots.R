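#' Plot methods for result objects
#'
#' `autoplot()` methods turn each result type into a ggplot: the mutation
#' spectrum becomes a bar chart of signed step sizes (insertions right of
#' zero, deletions left), rate estimates become a rate-versus-repeat-count
#' dot plot with confidence bars on a log scale, and a composition summary
#' becomes per-class locus counts faceted by unit length.
#'
#' @param object A result object (`msat_spectrum`, `msat_rates`, or
#'   `msat_composition`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name msat_plots
NULL

#' @rdname msat_plots
#' @importFrom ggplot2 autoplot
#' @method autoplot msat_spectrum
#' @export
autoplot.msat_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$step_sizes,
                  ggplot2::aes(x = .data$delta_units, y = .data$n_events,
                               fill = .data$delta_units > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = function(l) {
      seq(floor(l[1]), ceiling(l[2]))
    }) +
    ggplot2::labs(x = "Mutation size (repeat units)",
                  y = "Events",
                  title = "Mutation size spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname msat_plots
#' @method autoplot msat_rates
#' @export
autoplot.msat_rates <- function(object, ...) {
  d <- tidy(object)
  d <- d[!d$uninformative & !d$saturated & d$l > 0, , drop = FALSE]
  if (!"repeat_count" %in% names(d)) {
    abort("Rates table has no `repeat_count` column to plot against.")
  }
  d$perfection <- if ("percent_match" %in% names(d)) {
    ifelse(d$percent_match == 100, "perfect", "imperfect")
  } else "unknown"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$repeat_count, y = .data$mu,
                                  colour = .data$perfection)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = pmin(.data$ci_high,
                                                      max(.data$mu) * 10))) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Repeat count (units)",
                  y = "Mutation rate (per allele per generation)",
                  colour = NULL,
                  title = "Per-locus mutation rates") +
    ggplot2::theme_minimal()
}

#' @rdname msat_plots
#' @method autoplot msat_composition
#' @export
autoplot.msat_composition <- function(object, ...) {
  ggplot2::ggplot(object$class_counts,
                  ggplot2::aes(x = .data$canonical_class, y = .data$n_loci,
                               fill = .data$n_perfect > 0)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~unit_length, scales = "free_x") +
    ggplot2::labs(x = "Canonical motif class", y = "Loci",
                  fill = "Perfect loci present",
                  title = "Tandem-repeat composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
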