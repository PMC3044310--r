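# Diagnostic plots.

#' Histogram of attempt estimates
#'
#' The attempt histogram is the primary diagnostic: erroneous kmers pile up
#' near zero and genuine kmers peak near multiples of the coverage constant
#' `N(L - k + 1) / (|G| - k + 1)`.
#'
#' @param object An `attempt_em` fit.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attempt_em <- function(object, bins = 100, ...) {
  ggplot2::ggplot(object$estimates, ggplot2::aes(x = .data$attempts)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = "estimated attempts T", y = "kmers",
                  title = "Attempt-estimate histogram") +
    ggplot2::theme_minimal()
}

#' Wrong predictions versus threshold
#'
#' Plots `log10(WP + 1)` over the threshold grid; the curve is typically
#' U-shaped (false negatives dominate at low thresholds, false positives
#' at high ones).
#'
#' @param object A [wp_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = log10(.data$wp + 1))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold M", y = "log10(FP + FN + 1)",
                  title = "Wrong predictions vs threshold") +
    ggplot2::theme_minimal()
}

#' Mixture fit over the attempt histogram
#'
#' @param object An `attempt_mixture` fit.
#' @param T_est The attempt estimates the mixture was fitted to.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attempt_mixture <- function(object, T_est, bins = 100, ...) {
  grid <- seq(object$support[1], object$support[2], length.out = 512)
  dens <- tibble::tibble(t = grid, density = mixture_density(grid, object))
  ggplot2::ggplot(tibble::tibble(t = T_est), ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$density),
                       color = "firebrick") +
    ggplot2::labs(x = "estimated attempts T", y = "density",
                  title = "Gamma / Normals / Uniform mixture fit") +
    ggplot2::theme_minimal()
}

#' Compare Y- and T-threshold sweeps
#'
#' @param curve_y,curve_t [wp_curve()] results for observed counts and
#'   attempt estimates on the same kmer set.
#' @return A ggplot object overlaying both curves.
#' @export
plot_wp_comparison <- function(curve_y, curve_t) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(curve_y), statistic = "observed count Y"),
    dplyr::mutate(tibble::as_tibble(curve_t), statistic = "estimated attempts T")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = log10(.data$wp + 1),
                                   color = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold M", y = "log10(FP + FN + 1)", color = NULL) +
    ggplot2::theme_minimal()
}
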