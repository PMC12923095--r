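#' Percent-change bar chart across tasks, types and levels
#'
#' Bars of the relative performance change (percent of the unperturbed
#' baseline) per task, faceted by perturbation type, with one bar group per
#' level — the at-a-glance comparison of how much each perturbation family
#' hurts each task.
#'
#' @param bins Output of [robustness_bins()] (needs `task`, `ptype`, `level`,
#'   `delta`).
#' @return A ggplot object.
#' @export
plot_percent_change <- function(bins) {
  summ <- bins |>
    dplyr::group_by(.data$task, .data$ptype, .data$level) |>
    dplyr::summarise(pct_change = 100 * mean(.data$delta), .groups = "drop") |>
    dplyr::mutate(level = factor(.data$level))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$level, y = .data$pct_change,
                                     fill = .data$task)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~ptype) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "perturbation level (fraction of words)",
                  y = "% change vs original", fill = "task") +
    ggplot2::theme_minimal()
}

#' Median score by medical-term ratio bucket
#'
#' Lines of the median metric score across buckets of the fraction of
#' perturbed words that are medical terms, one line per perturbation level.
#'
#' @param profile Output of [medical_perturbation_profile()].
#' @return A ggplot object.
#' @export
plot_medical_profile <- function(profile) {
  profile <- dplyr::mutate(profile, level = factor(.data$level))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$ratio_mid,
                                        y = .data$median_score,
                                        colour = .data$level,
                                        group = .data$level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of perturbed words that are medical terms",
                  y = "median score", colour = "level") +
    ggplot2::theme_minimal()
}

#' @rdname plot_percent_change
#' @param object An `analysis_bundle` from [analyze_results()].
#' @param ... Unused.
#' @export
autoplot.analysis_bundle <- function(object, ...) {
  plot_percent_change(object$bins)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
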