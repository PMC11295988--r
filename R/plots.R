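# Group mean and normal-theory 95% CI over subjects.
group_ci <- function(data, grp, value) {
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(grp))),
    mean = mean(.data[[value]], na.rm = TRUE),
    se = stats::sd(.data[[value]], na.rm = TRUE) /
      sqrt(sum(!is.na(.data[[value]]))),
    .groups = "drop"
  )
}

#' Plot group lag-CRP curves
#'
#' Group mean conditional response probability by signed lag (subject means
#' +/- 95% CI), optionally split by a condition column such as
#' `oddball_type` or `anchor_role`. Forward and backward branches are drawn
#' separately (no line through lag 0).
#'
#' @param curves A tibble from [lag_crp()] or [anchored_crp()].
#' @param colour Optional name of a condition column mapped to colour.
#'
#' @return A ggplot object.
#' @export
plot_crp <- function(curves, colour = NULL) {
  grp <- c("lag", colour)
  g <- group_ci(curves, grp, "crp")
  g$branch <- ifelse(g$lag > 0, "forward", "backward")
  aes_args <- if (is.null(colour)) {
    ggplot2::aes(x = .data$lag, y = .data$mean, group = .data$branch)
  } else {
    ggplot2::aes(x = .data$lag, y = .data$mean,
                 colour = .data[[colour]],
                 group = interaction(.data$branch, .data[[colour]]))
  }
  ggplot2::ggplot(g, aes_args) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - 1.96 * .data$se,
      ymax = .data$mean + 1.96 * .data$se)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(g$lag))) +
    ggplot2::labs(x = "Lag (encoding positions)",
                  y = "Conditional response probability") +
    ggplot2::theme_minimal()
}

#' Plot percent recall by SOA
#'
#' Group mean percent of items recalled per list at each stimulus onset
#' asynchrony, with 95% CIs and jittered per-subject means.
#'
#' @param recall_by_soa Output of [total_recall_by_soa()].
#' @return A ggplot object.
#' @export
plot_recall_by_soa <- function(recall_by_soa) {
  g <- group_ci(recall_by_soa, "soa_s", "value")
  ggplot2::ggplot(g, ggplot2::aes(x = factor(.data$soa_s), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - 1.96 * .data$se,
      ymax = .data$mean + 1.96 * .data$se), width = 0.2) +
    ggplot2::geom_jitter(
      data = recall_by_soa,
      ggplot2::aes(x = factor(.data$soa_s), y = .data$value),
      width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "SOA (s)", y = "Items recalled per list (%)") +
    ggplot2::theme_minimal()
}

#' Plot the probability of first recall
#'
#' Group mean probability that the first correct recall comes from each
#' serial position.
#'
#' @param pfr Output of [probability_first_recall()].
#' @return A ggplot object.
#' @export
plot_pfr <- function(pfr) {
  g <- group_ci(pfr, "serial_position", "value")
  ggplot2::ggplot(g, ggplot2::aes(x = .data$serial_position, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - 1.96 * .data$se,
      ymax = .data$mean + 1.96 * .data$se)) +
    ggplot2::scale_x_continuous(breaks = unique(g$serial_position)) +
    ggplot2::labs(x = "Serial position", y = "Probability of first recall") +
    ggplot2::theme_minimal()
}

#' Plot anchored directional CRP cell means
#'
#' The 2x2 novelty-by-salience pattern: group mean anchored CRP (forward or
#' backward) for oddball vs control anchors in emotional and perceptual
#' lists.
#'
#' @param cells Output of [anchored_cell_means()].
#' @return A ggplot object.
#' @export
plot_anchored_cells <- function(cells) {
  g <- group_ci(cells, c("direction", "oddball_type", "anchor_role"),
                "mean_crp")
  ggplot2::ggplot(g, ggplot2::aes(x = .data$oddball_type, y = .data$mean,
                                  fill = .data$anchor_role)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - 1.96 * .data$se,
      ymax = .data$mean + 1.96 * .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "List type (salience)", y = "Mean CRP (+/- 5 lags)",
                  fill = "Anchor") +
    ggplot2::theme_minimal()
}
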