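#' Plot averaged normalized gait cycles
#'
#' @param norm tibble from [normalize_cycles()].
#' @return a ggplot: mean joint angle vs percent of gait cycle, one panel
#'   per joint.
#' @export
plot_normalized_cycle <- function(norm) {
  ggplot2::ggplot(norm, ggplot2::aes(.data$pct, .data$mean_deg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = "joint angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a hindlimb stick diagram
#'
#' Stance frames black, swing frames red, following the usual convention.
#'
#' @param segments tibble from [stick_diagram()].
#' @return a ggplot. The y axis is reversed (image coordinates).
#' @export
plot_stick_diagram <- function(segments) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend,
                               group = .data$frame)) +
    ggplot2::geom_segment(ggplot2::aes(color = .data$phase),
                          linewidth = 0.3, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(stance = "black",
                                           swing = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stimulation waveform window
#'
#' @param waveform tibble from [stim_waveform()].
#' @return a ggplot of DAC level vs time.
#' @export
plot_stim_waveform <- function(waveform) {
  ggplot2::ggplot(waveform, ggplot2::aes(.data$time_s, .data$level)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "DAC level (signed)") +
    ggplot2::theme_minimal()
}
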