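#' Plot a deformation profile
#'
#' Local z-shrinkage (percent) against normalized depth, with the mean
#' shrinkage as a dashed reference line.
#'
#' @param object A `deformation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.deformation_profile <- function(object, ...) {
  u <- seq(0, 1, length.out = 401)
  df <- tibble::tibble(depth = u, shrinkage = 100 * object$s(u))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$shrinkage)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 100 * object$cum_s(1), linetype = "dashed") +
    ggplot2::labs(x = "normalized depth (0 = top surface)",
                  y = "local z-shrinkage (%)",
                  title = sprintf("%s deformation profile", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot a kinetics fit
#'
#' Observed shrinkage over time with the fitted saturating-exponential
#' curve.
#'
#' @param object A `kinetics_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetics_fit <- function(object, ...) {
  tt <- seq(0, max(object$fitted$day) * 1.05, length.out = 300)
  curve <- tibble::tibble(day = tt,
                          fitted = object$s_inf * (1 - exp(-tt / object$tau)))
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::labs(x = "days after embedding", y = "z-shrinkage (%)",
                  title = sprintf("s_inf = %.1f%%, tau = %.2g d",
                                  object$s_inf, object$tau)) +
    ggplot2::theme_minimal()
}

#' Plot per-neuron lengths across conditions
#'
#' Total dendritic length per neuron under the baseline, deformed and
#' corrected conditions, with lines connecting measurements of the same
#' neuron.
#'
#' @param object A `replication_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.replication_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$lengths[c("neuron", "length_baseline", "length_deformed",
                     "length_corrected")],
    -"neuron", names_to = "condition", values_to = "length_um",
    names_prefix = "length_")
  long$condition <- factor(long$condition,
                           levels = c("baseline", "deformed", "corrected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition,
                                     y = .data$length_um,
                                     group = .data$neuron)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 2) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "total dendritic length (um)") +
    ggplot2::theme_minimal()
}
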