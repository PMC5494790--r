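#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of grid-search accuracy over (C, kernel parameter)
#'
#' @param object A `selm_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selm_grid
#' @export
autoplot.selm_grid <- function(object, ...) {
  lab <- if (object$family == "gaussian") expression(2 * sigma^2) else "m"
  ggplot2::ggplot(object$results,
                  ggplot2::aes(factor(.data$kernel_param), factor(.data$C),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$accuracy)), size = 2.7) +
    ggplot2::scale_fill_viridis_c(limits = c(NA, 1)) +
    ggplot2::labs(x = lab, y = "C", fill = "accuracy",
                  title = sprintf("%s cross-validated accuracy (%s kernel)",
                                  toupper(object$strategy), object$family)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a cross-validation run
#'
#' @param object A `selm_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selm_cv
#' @export
autoplot.selm_cv <- function(object, ...) {
  d <- tidy(object$confusion)
  ggplot2::ggplot(d, ggplot2::aes(.data$desired, .data$output,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "desired class", y = "output class",
                  title = sprintf("Pooled %d-fold confusion (accuracy %.3f)",
                                  object$k, object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a few EEG segments
#'
#' @param segments Segment tibble.
#' @param n_per_class Segments drawn (in row order) per class.
#' @param fs Sampling rate override.
#' @return A ggplot of amplitude (uV) against time, faceted by segment.
#' @export
plot_segments <- function(segments, n_per_class = 1, fs = NULL) {
  check_segments(segments)
  take <- segments |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  d <- take |>
    dplyr::mutate(t = purrr::map2(.data$samples, fs %||% .data$fs,
                                  function(x, f) seq_along(x) / f)) |>
    tidyr::unnest(c("samples", "t"))
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$samples)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~ .data$segment_id, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Per-class sensitivity as a function of the Gaussian kernel width
#'
#' Cross-validates at fixed `C` across a vector of `2sigma^2` values and
#' reports the per-class sensitivities — the input for a sensitivity-vs-width
#' figure.
#'
#' @param data Feature tibble.
#' @param two_sigma_sq_values Widths to evaluate.
#' @param C Box bound (default 5).
#' @param ... Passed to [cross_validate()].
#' @return Tibble with `two_sigma_sq`, `class`, `sensitivity`, `accuracy`.
#' @export
sensitivity_vs_width <- function(data,
                                 two_sigma_sq_values =
                                   grid_spec()$two_sigma_sq_values,
                                 C = 5, ...) {
  purrr::map(two_sigma_sq_values, function(w) {
    cv <- cross_validate(data, C = C,
                         kernel = kernel_spec("gaussian", two_sigma_sq = w),
                         ...)
    dplyr::mutate(cv$metrics[c("class", "sensitivity", "accuracy")],
                  two_sigma_sq = w, .before = 1)
  }) |> purrr::list_rbind()
}
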