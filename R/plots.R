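#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an uncertainty budget
#'
#' Bar chart of each component's share of the total variance of the
#' calibration factor.
#'
#' @param object An `uncertainty_budget`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uncertainty_budget
#' @export
autoplot.uncertainty_budget <- function(object, ...) {
  df <- tidy(object)
  df$component <- stats::reorder(df$component, df$share_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$share_pct, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "share of total variance (%)", y = NULL,
      title = sprintf(
        "u_rel(S_rc) = %.3g%%  [%s budget]",
        100 * object$u_rel_combined, object$method
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a half-life sweep
#'
#' Reproduces the structure of the clock-offset impact curves: combined
#' relative uncertainty against half-life, one curve per clock-offset
#' uncertainty, converging to the flat fixed-component baseline.
#'
#' @param object A [halflife_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot halflife_sweep
#' @export
autoplot.halflife_sweep <- function(object, ...) {
  df <- dplyr::mutate(object,
    offset = factor(sprintf("u(offset) = %.3g h", .data$u_offset_h),
      levels = sprintf("%s", sprintf(
        "u(offset) = %.3g h",
        sort(unique(.data$u_offset_h))
      ))
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$T_half_h, y = .data$u_rel_S_pct,
    colour = .data$offset
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "half-life (h)",
      y = "combined u_rel(S_rc) (%)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
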