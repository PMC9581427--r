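#' Psychometric function plot
#'
#' Observed proportion of high-frequency choices against signed unit
#' SNR, one line per cue (rule sessions) or per last-two-tone pattern
#' (stimulus sessions).
#'
#' @param trials Trial tibble with choices.
#' @return A ggplot.
#' @export
plot_psychometric <- function(trials) {
  trials <- filter_analyzable(trials)
  trials <- trials[trials$choice %in% c("L", "H"), ]
  trials$group <- psychometric_group(trials)
  df <- trials |>
    dplyr::group_by(.data$group, .data$snr_unit) |>
    dplyr::summarise(p_high = mean(.data$choice == "H"), n = dplyr::n(),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$snr_unit, .data$p_high,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "signed SNR (unit scale)", y = "P(choose high)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Chronometric function plot
#'
#' Median correct-trial RT against signed unit SNR per cue / pattern.
#'
#' @param trials Trial tibble with responses.
#' @return A ggplot.
#' @export
plot_chronometric <- function(trials) {
  trials <- filter_analyzable(trials)
  trials <- trials[!is.na(trials$correct) & trials$correct, ]
  trials$group <- psychometric_group(trials)
  df <- trials |>
    dplyr::group_by(.data$group, .data$snr_unit) |>
    dplyr::summarise(median_rt = stats::median(.data$rt_s), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$snr_unit, .data$median_rt,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "signed SNR (unit scale)", y = "median correct RT (s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

psychometric_group <- function(trials) {
  if (all(!is.na(trials$cue))) return(trials$cue)
  substr(trials$pretest, pmax(nchar(trials$pretest) - 1, 1),
         nchar(trials$pretest))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a performance landscape
#'
#' Normalized-accuracy surface with its proportion-of-maximum contour.
#'
#' @param object A [performance_grid()].
#' @param level Contour level (default 0.97).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.performance_grid <- function(object, level = 0.97, ...) {
  df <- tidy(object)
  ct <- contour_97(object, level)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$v)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$norm_accuracy)) +
    ggplot2::scale_fill_viridis_c(name = "prop. of max") +
    ggplot2::labs(x = "starting-point bias (z)",
                  y = "evidence-accumulation bias (v)",
                  title = paste(object$context, "context")) +
    ggplot2::theme_minimal()
  for (path in ct$paths) {
    p <- p + ggplot2::geom_path(data = path, colour = "white",
                                linewidth = 0.8)
  }
  p
}

#' Plot first-passage densities
#'
#' Choice-conditional decision-time densities from [solve_fpt()].
#'
#' @param object An `fpt_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fpt_solution <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$time, 2),
    density = c(object$dens_upper, object$dens_lower),
    bound = rep(c("upper (H)", "lower (L)"), each = length(object$time))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$density,
                                   colour = .data$bound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "decision time (s)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-bin pupil contrasts
#'
#' Time course of a contrast's across-subject coefficient with +/- 1 SE
#' ribbon; FDR-significant bins are marked.
#'
#' @param contrast_tbl Output of [timecourse_contrasts()].
#' @param q FDR threshold to mark (default 0.05).
#' @return A ggplot.
#' @export
plot_timecourse_contrasts <- function(contrast_tbl, q = 0.05) {
  ggplot2::ggplot(contrast_tbl,
                  ggplot2::aes(.data$bin_ms, .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$beta - .data$se,
                                      ymax = .data$beta + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$p_fdr < q),
                        colour = "darkgreen", size = 1.5) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "time from choice (ms)", y = "contrast beta (z)") +
    ggplot2::theme_minimal()
}
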