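#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the MAPD distribution of a cross-validation run
#'
#' One panel per property, substances as points over a violin of the MAPD
#' distribution, with the median annotated — the standard way to look at
#' how prediction errors distribute over a dataset.
#'
#' @param object A `vgc_cv` (or a list of them to compare methods).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vgc_cv <- function(object, ...) {
  df <- object$per_substance
  df$method <- object$method
  plot_mapd_distribution(df)
}

#' @rdname autoplot.vgc_cv
#' @param reports A list of `vgc_cv` objects (e.g. the vector-GC run and
#'   its mu = 0 benchmark) plotted side by side.
#' @export
plot_cv_comparison <- function(reports) {
  df <- dplyr::bind_rows(lapply(reports, function(r) {
    d <- r$per_substance; d$method <- r$method; d
  }))
  plot_mapd_distribution(df)
}

plot_mapd_distribution <- function(df) {
  med <- df |>
    dplyr::group_by(.data$method, .data$property) |>
    dplyr::summarise(median_mapd = stats::median(.data$mapd),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mapd,
                                   fill = .data$method)) +
    ggplot2::geom_violin(alpha = 0.4, scale = "width") +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.6) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(y = .data$median_mapd),
                        shape = 95, size = 10, colour = "black") +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "MAPD [%]",
                  title = "Held-out prediction deviations (LOO-CV)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Parity plot of predicted versus reference dipole moments
#'
#' @param predicted,reference Data frames with `substance_id` and `mu`
#'   (Debye), or named vectors.
#' @return A ggplot object with the bisector and the mean-absolute-
#'   deviation band.
#' @export
plot_dipole_parity <- function(predicted, reference) {
  as_df <- function(x, nm) {
    if (is.data.frame(x)) stats::setNames(x[, c("substance_id", "mu")],
                                          c("substance_id", nm))
    else tibble::tibble(substance_id = names(x), !!nm := unname(x))
  }
  df <- dplyr::inner_join(as_df(predicted, "mu_pred"),
                          as_df(reference, "mu_ref"), by = "substance_id")
  mad <- mean(abs(df$mu_pred - df$mu_ref))
  ggplot2::ggplot(df, ggplot2::aes(.data$mu_ref, .data$mu_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-mad, mad),
                         linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "reference dipole moment [D]",
                  y = "predicted dipole parameter [D]",
                  subtitle = sprintf("MAD = %.2f D, Pearson r = %.2f", mad,
                                     stats::cor(df$mu_pred, df$mu_ref))) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.vgc_cv
#' @export
autoplot.vgc_fit <- function(object, ...) {
  df <- tibble::tibble(evaluation = seq_along(object$history),
                       objective = object$history,
                       best = cummin(object$history))
  ggplot2::ggplot(df, ggplot2::aes(.data$evaluation, .data$best)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective), size = 0.3,
                        alpha = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "objective evaluation", y = "objective (best so far)",
                  title = "Regression convergence") +
    ggplot2::theme_bw()
}
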