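# ggplot2 views of the result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_ribbon autoplot
#'   labs scale_y_log10 facet_wrap position_jitter stat_summary theme_minimal
NULL

#' Plot a survey table
#'
#' Sparsity of every candidate transform at one error target, grouped by
#' dimensionality, with the per-dimensionality mean — the dimensionality-trend
#' view of the survey.
#'
#' @param object A `survey_table`.
#' @param target NMSE target to display.
#' @param metric Column to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survey_table <- function(object, target = 0.01, metric = "sparsity",
                                  ...) {
  tb <- dplyr::filter(tibble::as_tibble(object),
                      .data$target_nmse == !!target,
                      .data$status == "converged")
  tb$dim_label <- paste0(tb$dimensionality, "D ",
                         toupper(tb$transform))
  ggplot(tb, aes(x = .data$dim_label, y = .data[[metric]])) +
    geom_point(aes(colour = .data$family),
               position = position_jitter(width = 0.15, height = 0),
               alpha = 0.8) +
    stat_summary(fun = mean, geom = "point", shape = 95, size = 10,
                 colour = "black") +
    scale_y_log10() +
    labs(x = NULL, y = metric,
         title = sprintf("Candidate transforms at NMSE = %g", target)) +
    theme_minimal()
}

#' Plot a compactness curve
#'
#' Reconstruction error against the number of retained largest coefficients,
#' with the sorted coefficient magnitudes alongside.
#'
#' @param object A `compactness_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compactness_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$k, y = .data$nmse)) +
    geom_line() + geom_point() +
    scale_y_log10() +
    labs(x = "retained coefficients", y = "NMSE",
         title = sprintf("Compactness of %s (%dD)", object$wavelet,
                         object$dimensionality)) +
    theme_minimal()
}

#' Plot a spatiotemporal error profile
#'
#' @param object An `error_profile`.
#' @param ... Unused.
#' @return A ggplot of the two per-slice error distributions.
#' @export
autoplot.error_profile <- function(object, ...) {
  tb <- dplyr::bind_rows(
    tibble::tibble(profile = "temporal", index = seq_len(nrow(object$temporal)),
                   nmse = object$temporal$nmse),
    tibble::tibble(profile = "spatial", index = object$spatial$t,
                   nmse = object$spatial$nmse)
  )
  ggplot(tb[!is.na(tb$nmse), ], aes(x = .data$index, y = .data$nmse)) +
    geom_line() +
    facet_wrap(~profile, scales = "free_x") +
    labs(x = "sensor / frame index", y = "per-slice NMSE") +
    theme_minimal()
}

#' Plot a grand-average interaction
#'
#' @param object A `grand_average`.
#' @param ... Unused.
#' @return A ggplot of the mean activity with a standard-deviation band.
#' @export
autoplot.grand_average <- function(object, ...) {
  ggplot(object$template, aes(x = .data$frame, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "grey80") +
    geom_line() +
    labs(x = "aligned frame", y = "total activity",
         title = "Grand-average tactile interaction") +
    theme_minimal()
}
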