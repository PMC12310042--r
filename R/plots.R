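# ggplot2 displays ------------------------------------------------------------

#' Plot receptor localization time courses from a trajectory
#'
#' @param object a \code{vegfr_trajectory}.
#' @param receptors receptors to show.
#' @param normalize normalize each series to its t = 0 value.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vegfr_trajectory <- function(object,
                                      receptors = c("R1", "R2", "N1"),
                                      normalize = FALSE, ...) {
  series <- dplyr::bind_rows(lapply(receptors, function(r) {
    dplyr::bind_rows(lapply(c("surface", "internal", "whole_cell"),
                            function(loc) {
      s <- aggregate_receptor(object, r, loc)
      if (normalize) s <- normalize_to_control(s, s$value[1])
      s$receptor <- r
      s$location <- loc
      s
    }))
  }))
  ggplot2::ggplot(series,
                  ggplot2::aes(.data$time_s / 60, .data$value,
                               colour = .data$location)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~receptor, scales = "free_y") +
    ggplot2::labs(x = "time (min)",
                  y = if (normalize) "level (relative to t = 0)"
                      else "level (#/cell)",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot an internalization-multiplier scan
#'
#' Predicted localization ratios for each candidate multiplier over the
#' synthetic (or experimental) blot measurements, plus the SSE profile.
#'
#' @param object a \code{kint_scan}.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kint_scan <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$time_min, .data$ratio,
                               colour = factor(.data$multiplier))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(.data$time_min, .data$ratio),
                        inherit.aes = FALSE, alpha = 0.6) +
    ggplot2::facet_wrap(~localization) +
    ggplot2::labs(x = "time (min)", y = "VEGFR2 (relative to t = 0)",
                  colour = "kint fold") +
    ggplot2::theme_bw()
}

#' Plot decoy-effect dose dependence
#'
#' @param decoy tibble from [decoy_effect()] (may combine locations).
#' @return a ggplot.
#' @export
plot_decoy <- function(decoy) {
  ggplot2::ggplot(decoy,
                  ggplot2::aes(.data$dose_ng_ml, .data$decoy_pct,
                               colour = .data$location)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (ng/mL)", y = "decoy effect (%)", colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot a two-ligand competition grid as a heatmap
#'
#' @param grid tibble from [competition_grid()].
#' @param fill "value" or "reduction_pct".
#' @return a ggplot.
#' @export
plot_competition <- function(grid, fill = c("value", "reduction_pct")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(grid,
                  ggplot2::aes(factor(.data$dose_a), factor(.data$dose_b),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = paste(grid$ligand_a[1], "(ng/mL)"),
                  y = paste(grid$ligand_b[1], "(ng/mL)"),
                  fill = fill, title = grid$readout[1]) +
    ggplot2::theme_bw()
}

#' Plot Scatchard curves for one or more model variants
#'
#' @param points named list of tibbles from [scatchard()].
#' @return a ggplot.
#' @export
plot_scatchard <- function(points) {
  df <- dplyr::bind_rows(points, .id = "variant")
  ggplot2::ggplot(df, ggplot2::aes(.data$bound, .data$bound_over_free,
                                   colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bound (#/cell)", y = "bound / free", colour = NULL) +
    ggplot2::theme_bw()
}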