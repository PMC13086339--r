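# Figures for the derived quantities.  All return ggplot objects.

#' Plot the distribution of individual meal shares
#'
#' Boxplots of per-trial meal shares per fish, grouped by diet level and
#' ordered by decreasing median share, with the 12.5% even-split reference
#' line.
#'
#' @param x A [meal_shares()] table.
#' @return A ggplot object.
#' @export
plot_meal_shares <- function(x) {
  pt <- x$per_trial[!x$per_trial$waste, ]
  ord <- paste(x$per_fish$cage_id, x$per_fish$fish_index, sep = ":")
  pt$fish <- factor(paste(pt$cage_id, pt$fish_index, sep = ":"),
                    levels = ord)
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$fish, y = .data$share_pct,
                                   fill = .data$cage_id)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 12.5, linetype = "dashed") +
    ggplot2::facet_grid(. ~ diet_level, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "fish (sorted by decreasing median share)",
                  y = "meal share (%)", fill = "cage") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot observed versus model-expected pellet counts
#'
#' @param x A [predicted_counts()] table.
#' @return A ggplot object with the 1:1 reference line.
#' @export
plot_predicted_counts <- function(x) {
  fish <- x[!x$is_waste, ]
  ggplot2::ggplot(fish, ggplot2::aes(x = .data$observed,
                                     y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "observed pellets consumed",
                  y = "expected pellets (posterior mean)") +
    ggplot2::theme_bw()
}

#' Plot a clone-cage marginal-effect curve
#'
#' @param x A [clone_curve()] data frame.
#' @return A ggplot object: posterior-median curve with the 5th/95th
#'   percentile band as dashed lines.
#' @export
plot_clone_curve <- function(x) {
  lab <- switch(attr(x, "variable"),
                L2 = expression(L^2 ~ (cm^2)),
                S = "boats per trial (stress proxy)",
                T = "temperature (\u00b0C)",
                R = "delivered pellets (ration)")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$grid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q05), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q95), linetype = "dashed") +
    ggplot2::labs(x = lab, y = "per-fish consumption probability") +
    ggplot2::theme_bw()
}
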