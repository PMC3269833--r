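#' Plot methods
#'
#' `autoplot.bimodality_fit()` draws the expression histogram with the two
#' fitted Gaussian components overlaid (the visual check of a delta-AIC
#' call); `autoplot.trajectory()` plots the time courses of all circuit
#' states; `autoplot.hysteresis()` shows both sweep branches against the
#' stimulus, making the bistable window visible.
#'
#' @param object the fitted/simulated object.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot object.
#' @name switchscan-autoplot
NULL

#' @rdname switchscan-autoplot
#' @export
autoplot.bimodality_fit <- function(object, bins = 30, ...) {
  df <- augment.bimodality_fit(object)
  df <- df[!is.na(df$value), ]
  comp <- tidy.gmm_fit(object$fit2)
  grid <- seq(min(df$value), max(df$value), length.out = 200)
  dens <- purrr::pmap(comp, function(component, mode, weight, mean, variance, sd) {
    tibble::tibble(value = grid, mode = mode,
                   density = weight * dnorm(grid, mean, sd))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$mode),
                       linewidth = 1) +
    ggplot2::labs(title = if (is.na(object$gene_id)) NULL else object$gene_id,
                  subtitle = sprintf("delta AIC = %.1f", object$delta_aic),
                  x = "expression (log2)", y = "density", colour = "mode") +
    ggplot2::theme_minimal()
}

#' @rdname switchscan-autoplot
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object$states) |>
    dplyr::mutate(time = object$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "level")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$level,
                                   colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time", y = "expression level",
                  title = sprintf("%s, stimulus %g", object$model, object$stimulus)) +
    ggplot2::theme_minimal()
}

#' @rdname switchscan-autoplot
#' @export
autoplot.hysteresis <- function(object, ...) {
  df <- dplyr::filter(object$branches, .data$state == object$state)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$level,
                                        colour = .data$branch)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "stimulus", y = paste(object$state, "steady level"),
                  colour = "branch") +
    ggplot2::theme_minimal()
  if (isTRUE(object$window_width > 0)) {
    p <- p + ggplot2::annotate("rect", xmin = object$window_low,
                               xmax = object$window_high, ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "steelblue")
  }
  p
}

#' Histogram of delta-AIC scores across a compendium
#'
#' The genome-scale view of bimodality: most genes pile up at low delta AIC
#' (unimodal), a small tail of putative switches stands out on the right.
#'
#' @param scores a [score_bimodality()] table.
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 60) {
  df <- dplyr::filter(scores, !is.na(.data$delta_aic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aic)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "delta AIC (unimodal - bimodal)", y = "genes") +
    ggplot2::theme_minimal()
}
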