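#' Histogram of windowed diffusion coefficients
#'
#' Normalised histogram of per-window diffusion coefficients pooled across
#' molecules; on slide/stick cohorts the distribution is bimodal with modes
#' near 0 and the sliding D.
#'
#' @param windows Data.frame with a `D` column (e.g. row-bound
#'   [window_diffusion()] results).
#' @param binwidth Histogram bin width, bp^2 s^-1.
#' @param threshold Optional vertical reference line (the sliding
#'   threshold).
#' @return A ggplot object.
#' @export
plot_diffusion_histogram <- function(windows, binwidth = 2.5e3,
                                     threshold = 2.2e4) {
  p <- ggplot2::ggplot(windows, ggplot2::aes(x = .data$D)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = expression(D ~ (bp^2 ~ s^-1)), y = "Density") +
    ggplot2::theme_classic()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  p
}

#' Terminator-relative antisense peak frequency profile
#'
#' @param profile Data.frame from [distance_profile()].
#' @param control Optional data.frame with `distance`, `mean`, `sd` from
#'   control replicates.
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile, control = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$distance,
                                             y = .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$fraction - .data$sem, 0),
      ymax = .data$fraction + .data$sem)) +
    ggplot2::labs(x = "Distance from terminator (nt)",
                  y = "Fraction of windows with antisense peak") +
    ggplot2::theme_classic()
  if (!is.null(control))
    p <- p + ggplot2::geom_ribbon(
      data = control,
      ggplot2::aes(x = .data$distance, y = .data$mean,
                   ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      fill = "grey70", alpha = 0.5)
  p
}
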