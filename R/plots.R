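#' Plot an FLR curve
#'
#' False localization rate as a function of the score threshold, with an
#' optional horizontal reference at the target FLR.
#'
#' @param object A `phosphosim_flr` curve from [compute_flr_curve()].
#' @param target Optional FLR level drawn as a dashed reference line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot phosphosim_flr
#' @export
autoplot.phosphosim_flr <- function(object, target = 0.01, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$score, y = .data$flr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = paste0(attr(object, "score_field") %||% "score", " threshold"),
      y = "false localization rate"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    p <- p + ggplot2::geom_hline(yintercept = target, linetype = "dashed")
  }
  p
}

#' Plot a condition-sweep result
#'
#' Correct localizations at the target FLR per simulation condition,
#' faceted by scoring and coloured by neutral-loss template set.
#'
#' @param object A `phosphosim_sweep` tibble from [condition_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot phosphosim_sweep
#' @export
autoplot.phosphosim_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$intensity_label, y = .data$n_correct, fill = .data$nl_label
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scoring)) +
    ggplot2::labs(
      x = "pS/pT intact - NL-P - pY intact intensities (%)",
      y = "correct localizations at target FLR",
      fill = "NL templates"
    ) +
    ggplot2::theme_minimal()
}

#' Mirror plot of a query spectrum against a library entry
#'
#' Query peaks point up, library peaks point down; intensities are scaled
#' to their respective base peaks.
#'
#' @param query_peaks,library_peaks Peak tables.
#' @return A ggplot object.
#' @export
plot_spectrum_match <- function(query_peaks, library_peaks) {
  up <- dplyr::mutate(query_peaks,
                      rel = .data$intensity / max(.data$intensity), side = "query")
  down <- dplyr::mutate(library_peaks,
                        rel = -.data$intensity / max(.data$intensity), side = "library")
  df <- bind_rows(up[, c("mz", "rel", "side")], down[, c("mz", "rel", "side")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                                   yend = .data$rel, colour = .data$side)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Th)", y = "relative intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
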