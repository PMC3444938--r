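#' Half-life distribution of a turnover fit
#'
#' Histogram of uncensored half-lives on a log10 axis with the median
#' marked; censored and unfit proteins are reported in the subtitle.
#'
#' @param object A `turnover_fit` ([fit_turnover()]).
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_fit
#' @export
autoplot.turnover_fit <- function(object, bins = 40, ...) {
  ok <- dplyr::filter(tidy(object), .data$status == "ok")
  med <- median(ok$half_life_h)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$half_life_h)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = med, linetype = 2, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "protein half-life (h)", y = "proteins",
      title = sprintf("Median half-life %.1f h (%d proteins)", med, nrow(ok)),
      subtitle = sprintf("%d censored (k_deg <= 0), %d insufficient data",
                         sum(object$status == "censored_nonpositive_kdeg"),
                         sum(object$status == "insufficient_data"))
    )
}

#' Mean H/L ratio time course per condition
#'
#' The incorporation check: the mean protein ratio should increase
#' steadily with pulse time, with a shallower slope at higher salt.
#'
#' @param proteins Long protein tibble.
#' @param metadata Sample metadata tibble.
#' @return A ggplot object.
#' @export
plot_ratio_timecourse <- function(proteins, metadata) {
  data <- mean_ratio_by_sample(proteins) |>
    dplyr::inner_join(metadata, by = "sample_id") |>
    dplyr::group_by(.data$nacl_mM, .data$time_h) |>
    dplyr::summarise(mean_ratio = mean(.data$mean_ratio), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h, y = .data$mean_ratio,
                                     colour = factor(.data$nacl_mM))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pulse time (h)", y = "mean H/L ratio",
                  colour = "NaCl (mM)")
}

#' Cross-condition scatter of Z-normalized ratios
#'
#' Plots stress-condition Z-scores against the control, colouring shared
#' extreme responders, the view used to compare the two salt responses.
#'
#' @param ztab Tibble from [normalized_ratios()].
#' @param responders Optional [select_responders()] result.
#' @param control Control condition (default the smallest).
#' @return A ggplot object.
#' @export
plot_stress_scatter <- function(ztab, responders = NULL, control = NULL) {
  conds <- sort(unique(ztab$condition))
  if (is.null(control)) control <- conds[1]
  wide <- ztab |>
    dplyr::select("protein_id", "condition", "z") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "z") |>
    tidyr::drop_na()
  long <- wide |>
    tidyr::pivot_longer(-c("protein_id", !!as.character(control)),
                        names_to = "condition", values_to = "z") |>
    dplyr::rename(z_control = !!as.character(control))
  long$set <- "other"
  if (!is.null(responders)) {
    long$set[long$protein_id %in% responders$up] <- "up"
    long$set[long$protein_id %in% responders$down] <- "down"
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z_control, y = .data$z,
                                     colour = .data$set)) +
    ggplot2::geom_abline(linetype = 3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(other = "grey50", up = "firebrick",
                                            down = "steelblue")) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = sprintf("Z (control, %s mM)", control),
                  y = "Z (stress)", colour = NULL)
}

#' Dilution-series calibration plot
#'
#' Mean log10 abundance index per known concentration level with the
#' within-level spread; a straight, strictly increasing staircase means
#' the index tracks concentration over the full range.
#'
#' @param spread Tibble from [dilution_series_spread()].
#' @return A ggplot object.
#' @export
plot_dilution_series <- function(spread) {
  ggplot2::ggplot(spread, ggplot2::aes(x = .data$level, y = .data$mean_log10_ai)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_log10_ai - .data$sd_log10_ai,
      ymax = .data$mean_log10_ai + .data$sd_log10_ai)) +
    ggplot2::geom_line(linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "concentration level", y = "mean log10 abundance index")
}
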