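#' Tidy an evaluation report
#'
#' @param x A `link_eval` object from [run_missing()] or [run_spurious()].
#' @param ... Unused.
#' @return One row per measure and repetition: `measure`, `repetition`,
#'   `precision`, `n_positive`, `n_candidates`.
#' @export
tidy.link_eval <- function(x, ...) x$results

#' Summarize an evaluation report
#'
#' @inheritParams tidy.link_eval
#' @return One row per measure with `mean_precision`, `sd_precision`,
#'   `repetitions`, plus `protocol` and the random-guess baseline
#'   `baseline` (mean of `n_positive / n_candidates`).
#' @export
glance.link_eval <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean_precision = mean(.data$precision),
                     sd_precision = stats::sd(.data$precision),
                     repetitions = dplyr::n(),
                     baseline = mean(.data$n_positive / .data$n_candidates),
                     .groups = "drop") |>
    dplyr::mutate(protocol = x$protocol, .before = 1L)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an evaluation report
#'
#' Bar chart of mean precision per measure with +/- 1 sd error bars and the
#' random-guess baseline as a dashed line.
#'
#' @param object A `link_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.link_eval <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$measure,
                                  y = .data$mean_precision)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_precision - .data$sd_precision),
                   ymax = pmin(1, .data$mean_precision + .data$sd_precision)),
      width = 0.25) +
    ggplot2::geom_hline(yintercept = mean(g$baseline), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "precision",
                  title = sprintf("%s-link prediction precision",
                                  object$protocol)) +
    ggplot2::theme_minimal()
}

#' Plot a distance-bin link-probability curve
#'
#' @param object A `bin_curve` tibble from [distance_bin_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_curve <- function(object, ...) {
  mid <- (object$d_lo + object$d_hi) / 2
  ggplot2::ggplot(dplyr::mutate(object, d_mid = mid),
                  ggplot2::aes(x = .data$d_mid, y = .data$p_link)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hyperbolic distance (bin midpoint)",
                  y = "link probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
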