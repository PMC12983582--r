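#' Plot a power spectrum
#'
#' @param object An `eeg_spectrum`.
#' @param ... Unused.
#' @return A ggplot of log10 power against log10 frequency.
#' @method autoplot eeg_spectrum
#' @export
autoplot.eeg_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(power ~ (mu * V^2 / Hz)))
}

#' Plot a fitted spectrum model
#'
#' Overlays the observed log10 power, the full model and the aperiodic
#' component.
#'
#' @param object A `spectrum_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_model
#' @export
autoplot.spectrum_model <- function(object, ...) {
  df <- tibble(
    freq = object$freqs,
    observed = object$observed,
    model = object$fitted,
    aperiodic = aperiodic_values(object$freqs, object$offset, object$exponent)
  ) |>
    tidyr::pivot_longer(-"freq", names_to = "series", values_to = "log10_power")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$log10_power,
                                   color = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "log10 power")
}

#' Plot waveform motifs
#'
#' Shows each retained motif's IF-by-phase loading profile.
#'
#' @param object A `motif_model`.
#' @param ... Unused.
#' @return A ggplot faceted by component.
#' @method autoplot motif_model
#' @export
autoplot.motif_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$phase, y = .data$loading)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_x_continuous(
      breaks = c(-pi, 0, pi), labels = c("-π (trough)", "0 (peak)", "π")
    ) +
    ggplot2::labs(x = "phase", y = "IF loading")
}

#' Plot reconstructed normalized waveforms for selected motif scores
#'
#' Reconstructs the waveform associated with the motif model's mean profile
#' plus `score` times each motif, next to a reference sinusoid.
#'
#' @param model A `motif_model` fitted on *relative* (normalized) IF.
#' @param scores Named numeric vector of scores, one per plotted curve; by
#'   default one standard deviation of each component's observed scores.
#' @return A ggplot.
#' @export
plot_motif_waveforms <- function(model, scores = NULL) {
  stopifnot(inherits(model, "motif_model"))
  if (is.null(scores)) {
    scores <- apply(model$scores, 2, sd)
    names(scores) <- colnames(model$scores)
  }
  curves <- purrr::imap_dfr(scores, function(s, nm) {
    prof <- model$mean_profile + s * model$loadings[, nm]
    prof <- pmax(prof, 1e-6)
    dplyr::mutate(reconstruct_waveform(prof), curve = nm)
  })
  ref <- dplyr::mutate(reconstruct_waveform(rep(1, length(model$phase))),
                       curve = "sinusoid")
  ggplot2::ggplot(dplyr::bind_rows(curves, ref),
                  ggplot2::aes(x = .data$time, y = .data$waveform,
                               color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle fraction", y = "normalized amplitude")
}

#' Plot pre/post motif-score distributions
#'
#' @param scores A tibble from [motif_scores()] with a time-point column.
#' @param component Score column to plot.
#' @param time_col Name of the time-point column.
#' @return A ggplot of the two densities.
#' @export
plot_score_distributions <- function(scores, component = "PC1",
                                     time_col = "time_point") {
  stopifnot(component %in% names(scores), time_col %in% names(scores))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[component]],
                                       color = .data[[time_col]])) +
    ggplot2::geom_density() +
    ggplot2::labs(x = sprintf("%s score", component), y = "density")
}
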