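#' Plot an EEG recording
#'
#' Stacked per-channel traces, optionally over a time window.
#'
#' @param object an [eeg_recording()].
#' @param from,to time window in seconds (defaults: full trace).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, from = NULL, to = NULL, ...) {
  df <- as_tibble.eeg_recording(object) |>
    tidyr::pivot_longer(-"time", names_to = "channel", values_to = "uV")
  if (!is.null(from)) df <- dplyr::filter(df, .data$time >= from)
  if (!is.null(to)) df <- dplyr::filter(df, .data$time <= to)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$uV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot candidate waveforms
#'
#' Overlaid extraction-window waveforms, passing candidates split from
#' rejected ones, with the per-group mean highlighted.
#'
#' @param object a `spike_candidates` tibble.
#' @param max_waves cap on plotted waveforms per group.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spike_candidates <- function(object, max_waves = 200, ...) {
  if (!nrow(object)) abort("no candidates to plot")
  rate <- attr(object, "rate")
  pre <- attr(object, "pre")
  len <- length(object$waveform[[1]])
  t_ms <- ((seq_len(len) - 1) - round(pre / 1000 * rate)) / rate * 1000
  df <- object |>
    dplyr::group_by(.data$passed) |>
    dplyr::slice_head(n = max_waves) |>
    dplyr::ungroup()
  long <- tibble::tibble(
    id = rep(seq_len(nrow(df)), each = len),
    passed = rep(ifelse(df$passed, "passed", "rejected"), each = len),
    t_ms = rep(t_ms, nrow(df)),
    uV = unlist(df$waveform)
  )
  mean_df <- long |>
    dplyr::group_by(.data$passed, .data$t_ms) |>
    dplyr::summarise(uV = mean(.data$uV), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$uV, group = .data$id)) +
    ggplot2::geom_line(alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~passed) +
    ggplot2::labs(x = "time from vertex (ms)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot an embedding
#'
#' First two embedded coordinates of a candidate set, coloured by label.
#'
#' @param model an `lpp` fit.
#' @param candidates a (labeled) `spike_candidates` tibble.
#' @return A ggplot object.
#' @export
plot_embedding <- function(model, candidates) {
  Y <- lpp_transform(model, candidate_matrix(candidates))
  df <- tibble::tibble(
    y1 = Y[1, ],
    y2 = if (nrow(Y) >= 2) Y[2, ] else 0,
    label = as.character(candidates$label)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$y1, .data$y2, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation results
#'
#' Per-fold sensitivity, selectivity and F-score around the pooled
#' values.
#'
#' @param object a `spike_cv` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spike_cv <- function(object, ...) {
  df <- object$fold_metrics |>
    tidyr::pivot_longer(c("sensitivity", "selectivity", "fscore"),
                        names_to = "metric", values_to = "value")
  pooled <- object$metrics |>
    tidyr::pivot_longer(c("sensitivity", "selectivity", "fscore"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = pooled, colour = "red", shape = 4, size = 3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "per-fold distribution; pooled value marked") +
    ggplot2::theme_minimal()
}
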