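#' Topography of a spatial filter
#'
#' Flat-projected scalp map of the filter's back-projected topography
#' (or its raw weights).
#'
#' @param object An `fpvs_filter`.
#' @param what `"topography"` or `"weights"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpvs_filter <- function(object, what = c("topography", "weights"),
                                 ...) {
  what <- match.arg(what)
  m <- object$montage
  # azimuthal equidistant projection of the electrode positions
  pol <- acos(pmin(pmax(m$z, -1), 1))
  az <- atan2(m$y, m$x)
  df <- tibble(x = pol * cos(az), y = pol * sin(az),
               value = unname(object[[what]]), channel = m$channel)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_point(shape = 21, size = 5, colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s Hz spatial filter (%s)",
                                  format(object$f_target), what),
                  fill = what) +
    ggplot2::theme_void()
}

#' Mean amplitude spectrum of projected trials
#'
#' @param object An `fpvs_spectrum`.
#' @param fmax Upper frequency limit of the display (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpvs_spectrum <- function(object, fmax = 40, ...) {
  amp <- 2 * Mod(object$coef) / sum(object$window)
  keep <- object$freq <= fmax
  df <- tibble(frequency = object$freq[keep],
               amplitude = colMeans(amp)[keep])
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Condition-wise CS dot plot
#'
#' @param cs_table Tibble from [run_study()] or [cs_by_condition()].
#' @return A ggplot object.
#' @export
plot_cs <- function(cs_table) {
  df <- dplyr::mutate(cs_table,
                      cell = paste(.data$orientation, .data$regularity))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$cs,
                                        colour = .data$regularity)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                          colour = "black") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Cosine similarity index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if ("variability" %in% names(df) && length(unique(df$variability)) > 1) {
    p <- p + ggplot2::facet_wrap(~variability)
  }
  p
}

#' Forest plot of posterior contrasts
#'
#' @param contrasts Tibble from [contrast()] / [contrast_all()].
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  df <- dplyr::arrange(contrasts, .data$mean)
  df$contrast <- factor(df$contrast, levels = df$contrast)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$contrast,
                                   colour = .data$band)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_lower,
                                         xmax = .data$hdi_upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "CS difference (posterior mean, 95% HDI)", y = NULL,
                  colour = "evidence") +
    ggplot2::theme_minimal()
}

#' Posterior cell means of a fitted model
#'
#' @param object An `fpvs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpvs_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term %in% object$cells, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Posterior cell mean CS (95% HDI)", y = NULL) +
    ggplot2::theme_minimal()
}
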